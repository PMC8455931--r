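#' Steep sigmoid transfer function
#'
#' `S(a) = 1 / (1 + exp(-10 (a - 0.5)))`: the transfer function that maps a
#' continuous grey-wolf step onto a selection probability. Strictly
#' increasing with `S(0.5) = 0.5` and `S(a) + S(1 - a) = 1`.
#'
#' @param a Numeric vector.
#' @return Values in `(0, 1)`.
#' @export
#' @examples
#' sigmoid_transfer(c(0, 0.5, 1))
sigmoid_transfer <- function(a) 1 / (1 + exp(-10 * (a - 0.5)))

#' Binary position update from three donor bits
#'
#' The BGWO2 update: the new bit is 1 iff the sigmoid-transferred mean of
#' the three leader-derived donor bits reaches the random threshold,
#' `S((Y1 + Y2 + Y3) / 3) >= r0`.
#'
#' @param y1,y2,y3 Donor bit vectors (0/1) from the alpha, beta and delta
#'   wolves.
#' @param r0 Uniform random threshold(s) in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' binary_update(1, 1, 1, 0.9)   # S(1) ~ 0.993 >= 0.9 -> 1
binary_update <- function(y1, y2, y3, r0) {
  if (any(r0 < 0 | r0 > 1)) stop("r0 must lie in [0, 1]")
  as.integer(sigmoid_transfer((y1 + y2 + y3) / 3) >= r0)
}

#' Donor bits from one leader
#'
#' The continuous grey-wolf step toward a leader, computed on the binary
#' positions read as 0/1 reals (`A = 2 a r1 - a`, `C = 2 r2`,
#' `D = |C * leader - position|`, candidate `leader - A * D`), squashed
#' through [sigmoid_transfer()] and stochastically binarized against a
#' fresh uniform draw per dimension. As the control scalar `a` decays to 0
#' the donor concentrates on the leader's own bits (exploitation limit).
#'
#' Draws from the current R random stream; seed the caller for
#' reproducibility.
#'
#' @param position Current binary position (0/1 vector).
#' @param leader Leader's binary position, same length.
#' @param a Control scalar in `[0, 2]`, linearly decayed over iterations.
#' @return Integer 0/1 donor vector.
#' @export
donor_bits <- function(position, leader, a) {
  d <- length(position)
  stopifnot(length(leader) == d)
  A <- 2 * a * runif(d) - a
  C <- 2 * runif(d)
  D <- abs(C * leader - position)
  step <- leader - A * D
  as.integer(sigmoid_transfer(step) >= runif(d))
}

#' Default wrapper fitness for feature selection
#'
#' `w * err + (1 - w) * |mask| / d`, where `err` is the stratified k-fold
#' SVM cross-validation error on the selected columns and the second term
#' penalizes mask size. Lower is better; `w` close to 1 makes accuracy
#' dominate with sparsity as a tie-breaker. Deterministic given `seed`
#' (the same folds are reused for every candidate mask, making fitness
#' values comparable across masks).
#'
#' @param mask Logical or 0/1 vector over columns of `X`. An empty mask is
#'   repaired to one random bit (with a warning).
#' @param X Numeric feature matrix (rows = observations).
#' @param y Class labels aligned to rows.
#' @param folds Number of CV folds (default 6).
#' @param w Error/sparsity trade-off in `(0, 1]` (default 0.99).
#' @param seed Fold/SVM seed (default 0).
#' @param cost,gamma SVM hyperparameters, see [svm_cv()].
#' @return Scalar fitness (lower is better).
#' @export
default_fitness <- function(mask, X, y, folds = 6L, w = 0.99, seed = 0L,
                            cost = 1, gamma = NULL) {
  mask <- as.logical(mask)
  if (!any(mask)) {
    warning("empty mask repaired to one random bit")
    mask[sample.int(length(mask), 1L)] <- TRUE
  }
  rep_ <- svm_cv(X[, mask, drop = FALSE], y, k_folds = folds, seed = seed,
                 cost = cost, gamma = gamma)
  err <- 1 - rep_$acc / 100
  w * err + (1 - w) * sum(mask) / length(mask)
}

#' Binary grey wolf feature selection (BGWO2)
#'
#' Wrapper feature selection over the columns of a feature matrix. A pack
#' of binary wolves explores masks; the three best-so-far positions (alpha,
#' beta, delta) steer every wolf through [donor_bits()] and
#' [binary_update()], with the control scalar decaying linearly from 2 to 0
#' across iterations. Bookkeeping is elitist, so the best-so-far fitness
#' trace is non-increasing, and the whole run is reproducible from `seed`.
#'
#' @param X Numeric matrix (or `feature_matrix`), observations x columns,
#'   at least 2 columns.
#' @param y Class labels aligned to rows; at least two distinct classes.
#' @param pack_size Number of wolves (default 8).
#' @param iters Iterations `T` (default 70).
#' @param fitness Function `(mask) -> scalar` to minimize; defaults to
#'   [default_fitness()] on `X`, `y` with the parameters below.
#' @param folds,w,cost,gamma Passed to [default_fitness()] when `fitness`
#'   is not supplied.
#' @param seed Integer seed governing every random draw of the run.
#' @return An object of class `bgwo_selection`: `mask` (logical), its
#'   `n_selected`, `best_fitness`, the per-iteration `fitness_trace`, the
#'   final `pack` state (positions, fitness, leaders) and the `config`.
#' @export
bgwo_select <- function(X, y, pack_size = 8L, iters = 70L, fitness = NULL,
                        folds = 6L, w = 0.99, cost = 1, gamma = NULL,
                        seed = 0L) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d < 2) stop("need at least 2 columns to select over")
  y <- factor(y)
  if (nlevels(y) < 2) stop("labels are degenerate: a single class")
  if (is.null(fitness)) {
    fitness <- function(mask) default_fitness(mask, X, y, folds = folds,
                                              w = w, seed = seed,
                                              cost = cost, gamma = gamma)
  }
  with_rng_seed(seed, {
    pos <- matrix(rbinom(pack_size * d, 1L, 0.5), pack_size, d)
    for (i in seq_len(pack_size)) {
      if (!any(pos[i, ] == 1L)) pos[i, sample.int(d, 1L)] <- 1L
    }
    fit <- vapply(seq_len(pack_size), function(i) fitness(pos[i, ]), 0)
    ord <- order(fit)[seq_len(min(3L, pack_size))]
    leaders <- lapply(ord, function(i) list(pos = pos[i, ], fit = fit[i]))
    while (length(leaders) < 3L) leaders <- c(leaders, leaders[length(leaders)])
    trace <- numeric(iters)
    for (t in seq_len(iters)) {
      a <- 2 * (1 - t / iters)
      for (i in seq_len(pack_size)) {
        y1 <- donor_bits(pos[i, ], leaders[[1]]$pos, a)
        y2 <- donor_bits(pos[i, ], leaders[[2]]$pos, a)
        y3 <- donor_bits(pos[i, ], leaders[[3]]$pos, a)
        newpos <- binary_update(y1, y2, y3, runif(d))
        if (!any(newpos == 1L)) newpos[sample.int(d, 1L)] <- 1L
        pos[i, ] <- newpos
        fit[i] <- fitness(newpos)
      }
      # elitist leader update: earlier-evaluated wins ties (stable order)
      cand_fit <- c(vapply(leaders, `[[`, 0, "fit"), fit)
      cand_pos <- rbind(do.call(rbind, lapply(leaders, `[[`, "pos")), pos)
      ord <- order(cand_fit)[1:3]
      leaders <- lapply(ord, function(i)
        list(pos = cand_pos[i, ], fit = cand_fit[i]))
      trace[t] <- leaders[[1]]$fit
    }
  })
  mask <- as.logical(leaders[[1]]$pos)
  structure(list(mask = mask, n_selected = sum(mask),
                 best_fitness = leaders[[1]]$fit, fitness_trace = trace,
                 pack = list(positions = pos, fitness = fit,
                             alpha = leaders[[1]], beta = leaders[[2]],
                             delta = leaders[[3]]),
                 config = list(pack_size = pack_size, iters = iters,
                               folds = folds, w = w, cost = cost,
                               gamma = gamma, seed = seed, n_dims = d)),
            class = "bgwo_selection")
}

#' @export
print.bgwo_selection <- function(x, ...) {
  cat(sprintf("<bgwo_selection> %d / %d columns selected, best fitness %.5f (pack %d, %d iters, seed %s)\n",
              x$n_selected, x$config$n_dims, x$best_fitness,
              x$config$pack_size, x$config$iters, x$config$seed))
  invisible(x)
}
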