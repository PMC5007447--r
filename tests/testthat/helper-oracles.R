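## Independent oracles used by the tests: a dense Moore-Penrose
## implementation of the edge-to-edge transfer matrix, and a brute-force
## minimiser of the tilted quantile loss.

## Dense transfer-matrix columns: G B L^+ B^T restricted to source bonds,
## with the pseudo-inverse computed explicitly (MASS::ginv).
oracle_transfer <- function(graph, srcIds) {
  b <- bonds(graph)
  n <- nrow(nodes(graph))
  m <- nrow(b)
  B <- matrix(0, m, n)
  B[cbind(seq_len(m), b$from)] <- 1
  B[cbind(seq_len(m), b$to)] <- -1
  L <- t(B) %*% (b$energy * B)
  Lp <- MASS::ginv(L)
  M <- (b$energy * B) %*% Lp %*% t(B)
  M[, match(srcIds, b$id), drop = FALSE]
}

## Brute-force propensities for a site given as residue keys: sources are
## the weak bonds with exactly one endpoint in the site.
oracle_propensity <- function(graph, siteResidues) {
  b <- bonds(graph)
  src <- b$id[xor(b$res1 %in% siteResidues, b$res2 %in% siteResidues) & b$weak]
  M <- oracle_transfer(graph, src)
  raw <- rowSums(abs(M))
  scored <- !(b$id %in% src)
  norm <- ifelse(scored, raw / sum(raw[scored]), NA_real_)
  list(src = src, raw = raw, norm = norm, scored = scored)
}

## Brute-force linear quantile regression: the optimum interpolates as
## many points as parameters, so enumerate all interpolating subsets.
brute_qr <- function(y, x = NULL, p) {
  n <- length(y)
  X <- if (is.null(x)) matrix(1, n, 1) else cbind(1, x)
  m <- ncol(X)
  tl <- function(beta) {
    r <- y - as.numeric(X %*% beta)
    sum(r * (p - (r < 0)))
  }
  best <- Inf; bb <- NULL
  for (s in asplit(utils::combn(n, m), 2L)) {
    Xs <- X[s, , drop = FALSE]
    if (abs(det(Xs)) < 1e-12) next
    beta <- solve(Xs, y[s])
    l <- tl(beta)
    if (l < best) { best <- l; bb <- beta }
  }
  list(coef = bb, loss = best)
}

## Shared multi-protein reference model (expensive; fitted once per run).
.cache <- new.env(parent = emptyenv())
reference_model_cached <- function() {
  if (is.null(.cache$refmodel)) {
    tr <- simulateReferenceTriplets(seed = 301L)
    .cache$refmodel <- fitReferenceModel(tr)
  }
  .cache$refmodel
}
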