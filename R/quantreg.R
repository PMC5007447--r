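## Linear quantile regression by minimising the tilted absolute loss
##   sum_i rho_p(y_i - b0 - b' x_i),  rho_p(u) = u (p - I(u < 0)).
## The minimisation is convex and its optimum is attained at a vertex that
## interpolates as many observations as there are parameters. We descend
## with the Hunter-Lange epsilon-smoothed majorise-minimise iteration
## (each step a weighted least-squares solve), then polish to an exact
## vertex by enumerating interpolating subsets among the smallest
## residuals. The polished solution is LP-exact: it satisfies the
## subgradient condition (counts of negative / non-positive residuals
## bracket p*n).

tilted_loss <- function(r, p) sum(r * (p - (r < 0)))

#' Linear quantile regression
#'
#' Estimates the conditional p-th quantile \eqn{Q_p(x) = \beta_0 + \beta'x}
#' by minimising the tilted absolute loss. With no covariates the exact
#' sample quantile (lower LP vertex) is returned.
#'
#' @param y numeric response.
#' @param x covariate matrix (or vector, or NULL for intercept-only); a
#'   column of ones is added internally.
#' @param p quantile level in (0, 1).
#' @return named numeric vector of coefficients (intercept first) with
#'   attribute \code{loss}, the attained tilted loss.
#' @export
quantileRegress <- function(y, x = NULL, p = 0.5) {
  stopifnot(is.numeric(y), length(p) == 1L, p > 0, p < 1)
  n <- length(y)
  if (is.null(x)) {
    X <- matrix(1, n, 1L)
  } else {
    x <- as.matrix(x)
    stopifnot(nrow(x) == n)
    X <- cbind(1, x)
  }
  m <- ncol(X)
  if (n <= m - 1L || n < m)
    stop("need more observations than covariates")
  if (qr(X)$rank < m)
    stop("covariate matrix is rank deficient")

  if (m == 1L) {
    ## intercept-only: LP vertex is an order statistic
    ys <- sort(y)
    np <- n * p
    k <- if (abs(np - round(np)) < 1e-9) as.integer(round(np)) else ceiling(np)
    k <- min(max(k, 1L), n)
    beta <- ys[k]
    r <- y - beta
    return(structure(c(intercept = beta), loss = tilted_loss(r, p)))
  }

  ## ---- epsilon-smoothed MM descent ----
  beta <- tryCatch(qr.solve(X, y), error = function(e) rep(0, m))
  scale <- max(sd(y), 1e-8)
  eps <- 1e-6 * scale
  for (it in seq_len(300L)) {
    r <- y - X %*% beta
    w <- 1 / (eps + abs(r))
    A <- crossprod(X, X * as.numeric(w))
    bvec <- crossprod(X, as.numeric(w) * y) + (2 * p - 1) * colSums(X)
    newbeta <- tryCatch(solve(A, bvec), error = function(e) beta)
    if (max(abs(newbeta - beta)) < 1e-11 * scale) { beta <- newbeta; break }
    beta <- newbeta
  }
  beta <- as.numeric(beta)
  r <- as.numeric(y - X %*% beta)
  best_loss <- tilted_loss(r, p)

  ## ---- exact vertex polish: the optimum interpolates m observations ----
  k <- min(n, 3L * m + 3L)
  cand <- order(abs(r))[seq_len(k)]
  subs <- combn(cand, m)
  vbeta <- NULL; vloss <- Inf
  for (s in seq_len(ncol(subs))) {
    idx <- subs[, s]
    Xs <- X[idx, , drop = FALSE]
    bs <- tryCatch(solve(Xs, y[idx]), error = function(e) NULL)
    if (is.null(bs) || any(!is.finite(bs))) next
    ls <- tilted_loss(as.numeric(y - X %*% bs), p)
    if (ls < vloss) { vloss <- ls; vbeta <- as.numeric(bs) }
  }
  if (!is.null(vbeta) && vloss <= best_loss + 1e-7 * (1 + abs(best_loss))) {
    beta <- vbeta
    best_loss <- vloss
  }
  nm <- c("intercept",
          if (!is.null(colnames(X)) && m > 1L) colnames(X)[-1] else
            paste0("b", seq_len(m - 1L)))
  nm[nm == ""] <- paste0("b", which(nm == ""))
  structure(setNames(beta, nm[seq_len(m)]), loss = best_loss)
}
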