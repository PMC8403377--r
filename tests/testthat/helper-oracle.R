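# Independent brute-force oracles. These deliberately share no code with the
# package internals: path enumeration instead of forward-backward, pair
# counting instead of rank formulas, mean-absolute-difference instead of the
# Lorenz trapezoid.

# Posterior genotype probabilities of a diploid copying model by exhaustive
# enumeration over all (K^2)^M ordered-pair state paths.
oracle_diploid_posterior <- function(H, pos, lik, switch_rate, mu) {
  K <- nrow(H); M <- ncol(H)
  states <- expand.grid(i = seq_len(K), j = seq_len(K))
  S <- nrow(states)
  d_of <- function(m, s) H[states$i[s], m] + H[states$j[s], m]
  pmis <- rbind(c((1 - mu)^2, 2 * mu * (1 - mu), mu^2),
                c(mu * (1 - mu), (1 - mu)^2 + mu^2, mu * (1 - mu)),
                c(mu^2, 2 * mu * (1 - mu), (1 - mu)^2))
  emis <- function(m, s) sum(pmis[d_of(m, s) + 1, ] * lik[m, ])
  trans1 <- function(a, b, s) (1 - s) * (a == b) + s / K
  sw <- c(0, 1 - exp(-switch_rate * diff(pos)))

  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
  gp <- matrix(0, M, 3)
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    w <- 1 / S
    for (m in 2:max(M, 2)) {
      if (m > M) break
      w <- w * trans1(states$i[path[m - 1]], states$i[path[m]], sw[m]) *
        trans1(states$j[path[m - 1]], states$j[path[m]], sw[m])
    }
    if (w == 0) next
    full_emis <- vapply(seq_len(M), function(m) emis(m, path[m]),
                        numeric(1))
    for (m in seq_len(M)) {
      rest <- prod(full_emis[-m])
      d <- d_of(m, path[m])
      for (g in 0:2)
        gp[m, g + 1] <- gp[m, g + 1] +
          w * rest * pmis[d + 1, g + 1] * lik[m, g + 1]
    }
  }
  gp / rowSums(gp)
}

# AUC by explicit case-control pair counting (ties worth one half).
oracle_auc <- function(scores, labels) {
  ca <- scores[labels == 1]; co <- scores[labels == 0]
  tot <- 0
  for (a in ca) for (b in co)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(co))
}

# Confusion-count concordance metrics by explicit loops.
oracle_ndr <- function(truth, imp) {
  disc <- 0; denom <- 0
  for (k in seq_along(truth)) {
    if (truth[k] > 0 || imp[k] > 0) {
      denom <- denom + 1
      if (truth[k] != imp[k]) disc <- disc + 1
    }
  }
  if (denom == 0) NA_real_ else disc / denom
}

oracle_fpr_fnr <- function(truth, imp) {
  fp <- 0; nref <- 0; fn <- 0; nalt <- 0
  for (k in seq_along(truth)) {
    if (truth[k] == 0) {
      nref <- nref + 1
      if (imp[k] > 0) fp <- fp + 1
    } else {
      nalt <- nalt + 1
      if (imp[k] == 0) fn <- fn + 1
    }
  }
  c(if (nref) fp / nref else NA_real_, if (nalt) fn / nalt else NA_real_)
}

# Gini via the relative mean absolute difference.
oracle_gini <- function(x) {
  n <- length(x)
  tot <- 0
  for (a in x) for (b in x) tot <- tot + abs(a - b)
  tot / (2 * n^2 * mean(x))
}

# Pearson r^2 by the textbook sum formula.
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Genotype likelihoods as per-read products (binomial coefficient cancels
# under normalization).
oracle_gl <- function(n_ref, n_alt, e) {
  p <- c(e, 0.5, 1 - e)
  l <- p^n_alt * (1 - p)^n_ref
  l / sum(l)
}

# Tiny panel fixture used across HMM tests.
tiny_panel <- function(alleles, positions = NULL, region_length = 1000) {
  K <- nrow(alleles); M <- ncol(alleles)
  storage.mode(alleles) <- "integer"
  structure(list(positions = as.integer(positions %||% seq(100, by = 100,
                                                           length.out = M)),
                 alleles = alleles,
                 site_ids = sprintf("snp%05d", seq_len(M)),
                 ref = rep("A", M), alt = rep("G", M),
                 region_length = region_length),
            class = "hap_panel")
}

make_gl <- function(lin, panel, depth = NULL) {
  # lin: n x M x 3 linear likelihoods
  n <- dim(lin)[1]; M <- dim(lin)[2]
  structure(list(loglik = log(lin),
                 depth = depth %||% matrix(1L, n, M),
                 error_rate = 0.01, site_ids = panel$site_ids,
                 positions = panel$positions, ref = panel$ref,
                 alt = panel$alt),
            class = "geno_lik")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
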