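#' Sum of nearest-center distances (the clustering objective)
#'
#' A candidate solution is a concatenation of two D-dimensional cluster
#' centers. Each data point contributes its Euclidean distance to the nearer
#' of the two centers; the objective is the sum over all points.
#'
#' @param position Numeric vector of length 2*D: `c(center1, center2)`.
#' @param data Numeric matrix, n x D (rows are points), or a vector for D=1.
#' @return Non-negative scalar objective value.
#' @examples
#' X <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
#' sum_distance(c(0, 1, 10, 1), X)  # 4
#' @export
sum_distance <- function(position, data) {
  X <- .as_points(data)
  D <- ncol(X)
  if (length(position) != 2L * D)
    stop(sprintf("position length %d does not match 2 x %d data dimensions",
                 length(position), D), call. = FALSE)
  c1 <- position[seq_len(D)]
  c2 <- position[D + seq_len(D)]
  d1 <- sqrt(rowSums((X - matrix(c1, nrow(X), D, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((X - matrix(c2, nrow(X), D, byrow = TRUE))^2))
  sum(pmin(d1, d2))
}

.as_points <- function(data) {
  X <- if (is.matrix(data)) data else matrix(as.numeric(data), ncol = 1L)
  if (!is.numeric(X) || nrow(X) < 1L || anyNA(X))
    stop("'data' must be a numeric matrix of points without NAs",
         call. = FALSE)
  X
}

#' UDLM configuration
#'
#' @param pop_size Number of particles (>= 1; >= 2 for pairwise learning).
#'   Default 30.
#' @param max_iter Iterations. Default 200.
#' @param init_bounds Optional 2 x (2*D) matrix of `rbind(low, high)`
#'   initialization bounds per coordinate; default: the per-feature data
#'   range, replicated for both centers. Bounds constrain initialization
#'   only — learning steps are never clamped.
#' @param seed Integer RNG seed; required for reproducible runs.
#' @return A `udlm_config` list.
#' @export
udlm_config <- function(pop_size = 30L, max_iter = 200L, init_bounds = NULL,
                        seed = 1L) {
  pop_size <- as.integer(pop_size); max_iter <- as.integer(max_iter)
  if (is.na(pop_size) || pop_size < 1L) stop("'pop_size' must be >= 1",
                                             call. = FALSE)
  if (is.na(max_iter) || max_iter < 1L) stop("'max_iter' must be >= 1",
                                             call. = FALSE)
  if (!is.null(init_bounds)) {
    if (!is.matrix(init_bounds) || nrow(init_bounds) != 2L ||
        any(init_bounds[1L, ] > init_bounds[2L, ]))
      stop("'init_bounds' must be rbind(low, high) with low <= high",
           call. = FALSE)
  }
  structure(list(pop_size = pop_size, max_iter = max_iter,
                 init_bounds = init_bounds, seed = as.integer(seed)),
            class = "udlm_config")
}

#' Initialize the particle swarm
#'
#' Scatters `pop_size` particles uniformly within the initialization bounds
#' (default: per-feature data range, replicated for both encoded centers).
#' Personal bests start at the initial positions; the global best is the best
#' personal best. Seeds the RNG from `config$seed`, so the same seed always
#' yields the same swarm.
#'
#' @param data Point matrix (n x D).
#' @param config A [udlm_config()].
#' @return A `swarm_state` list: `pbest` (pop x 2D matrix), `pbest_value`,
#'   `gbest_position`, `gbest_value`, `iteration`, `history`, `seed`.
#' @export
initialize_swarm <- function(data, config = udlm_config()) {
  X <- .as_points(data)
  D <- ncol(X)
  set.seed(config$seed)
  b <- config$init_bounds
  if (is.null(b)) {
    lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
    b <- rbind(rep(lo, 2L), rep(hi, 2L))
  }
  if (ncol(b) != 2L * D)
    stop("init_bounds width must be 2 x data dimension", call. = FALSE)
  P <- config$pop_size
  pos <- matrix(runif(P * 2L * D), P, 2L * D)
  pos <- sweep(pos, 2L, b[2L, ] - b[1L, ], `*`)
  pos <- sweep(pos, 2L, b[1L, ], `+`)
  val <- apply(pos, 1L, sum_distance, data = X)
  g <- which.min(val)
  structure(list(pbest = pos, pbest_value = val,
                 gbest_position = pos[g, ], gbest_value = val[g],
                 iteration = 0L, history = val[g], seed = config$seed),
            class = "swarm_state")
}

#' One Gaussian pairwise-learning step
#'
#' Given an ordered pair of particles — `p_j` the one with the smaller
#' (better) objective, `p_i` the larger — proposes new candidate positions:
#' the loser samples per-coordinate from a Gaussian centered midway between
#' the pair with spread equal to their separation; the winner samples from a
#' Gaussian centered midway between itself and the global best with spread
#' equal to that separation. A zero spread yields the mean exactly, so a
#' particle already at the global best proposes itself.
#'
#' @param p_i Position (personal best) of the worse particle, length 2*D.
#' @param p_j Position of the better particle, length 2*D.
#' @param gbest Global best position, length 2*D.
#' @return List with `candidate_i` and `candidate_j` vectors.
#' @export
pairwise_learning_step <- function(p_i, p_j, gbest) {
  k <- length(p_i)
  if (length(p_j) != k || length(gbest) != k)
    stop("p_i, p_j and gbest must have equal length", call. = FALSE)
  alpha <- (p_i + p_j) / 2
  beta  <- abs(p_i - p_j)
  chi   <- (p_j + gbest) / 2
  delta <- abs(p_j - gbest)
  list(candidate_i = rnorm(k, mean = alpha, sd = beta),
       candidate_j = rnorm(k, mean = chi, sd = delta))
}

#' Run the unsupervised dynamic learning mechanism
#'
#' Two-center clustering by a particle population. Each iteration, every
#' particle is paired with one uniformly random distinct neighbor; the pair
#' is ordered by personal-best objective and both members propose candidates
#' via [pairwise_learning_step()]. A candidate replaces its owner's personal
#' best only if it strictly improves the [sum_distance()] objective; the
#' global best is refreshed after every evaluation, so the global-best
#' history is non-increasing. Fully reproducible from `config$seed`.
#'
#' @param data Point matrix (n x D) or vector (D = 1).
#' @param config A [udlm_config()].
#' @return List with `centers` (2 x D matrix, rows are the two centers),
#'   `objective` (final global-best value) and `state` (the final
#'   `swarm_state`, including per-iteration `history` of the global best).
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
#' fit <- run_udlm(X, udlm_config(pop_size = 20, max_iter = 60, seed = 7))
#' fit$centers
#' @export
run_udlm <- function(data, config = udlm_config()) {
  X <- .as_points(data)
  D <- ncol(X)
  st <- initialize_swarm(X, config)
  P <- config$pop_size
  for (t in seq_len(config$max_iter)) {
    for (i in seq_len(P)) {
      j <- if (P > 1L) seq_len(P)[-i][sample.int(P - 1L, 1L)] else i
      # the member with the smaller objective plays the "winner" role j
      if (st$pbest_value[j] <= st$pbest_value[i]) {
        wi <- i; wj <- j
      } else {
        wi <- j; wj <- i
      }
      cand <- pairwise_learning_step(st$pbest[wi, ], st$pbest[wj, ],
                                     st$gbest_position)
      for (who in list(c(wi, 1L), c(wj, 2L))) {
        idx <- who[1L]
        pos <- if (who[2L] == 1L) cand$candidate_i else cand$candidate_j
        v <- sum_distance(pos, X)
        if (v < st$pbest_value[idx]) {
          st$pbest[idx, ] <- pos
          st$pbest_value[idx] <- v
          if (v < st$gbest_value) {
            st$gbest_value <- v
            st$gbest_position <- pos
          }
        }
      }
    }
    st$iteration <- t
    st$history <- c(st$history, st$gbest_value)
  }
  centers <- rbind(st$gbest_position[seq_len(D)],
                   st$gbest_position[D + seq_len(D)])
  rownames(centers) <- c("center1", "center2")
  list(centers = centers, objective = st$gbest_value, state = st)
}

#' Assign points to the nearer of two centers
#'
#' @param data Point matrix (n x D) or vector.
#' @param centers 2 x D matrix (rows are centers) or length-2*D vector.
#' @return Integer vector of cluster indices in `{0, 1}` (0 = first center;
#'   exact ties go to 0).
#' @export
assign_labels <- function(data, centers) {
  X <- .as_points(data)
  D <- ncol(X)
  cc <- if (is.matrix(centers)) as.vector(t(centers)) else centers
  if (length(cc) != 2L * D)
    stop("centers do not match data dimension", call. = FALSE)
  c1 <- cc[seq_len(D)]; c2 <- cc[D + seq_len(D)]
  d1 <- sqrt(rowSums((X - matrix(c1, nrow(X), D, byrow = TRUE))^2))
  d2 <- sqrt(rowSums((X - matrix(c2, nrow(X), D, byrow = TRUE))^2))
  as.integer(d2 < d1)
}
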