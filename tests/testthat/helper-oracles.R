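# Independent reference implementations used as oracles.  These are kept
# deliberately naive (enumeration, textbook formulas) and share no code
# with the package internals they check.

# Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# exact two-sided rank-sum p by enumeration of all group assignments
oracle_wilcox_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# AUC by explicit pairwise concordance with half credit for ties
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# textbook pooled / Welch t and two-sided variance-ratio F
oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}
oracle_t_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  se2 <- var(a) / na + var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / na)^2 / (na - 1) + (var(b) / nb)^2 / (nb - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
oracle_f_test <- function(a, b) {
  va <- var(a); vb <- var(b)
  if (va >= vb) {
    f <- va / vb
    p <- 2 * pf(f, length(a) - 1, length(b) - 1, lower.tail = FALSE)
  } else {
    f <- vb / va
    p <- 2 * pf(f, length(b) - 1, length(a) - 1, lower.tail = FALSE)
  }
  list(f = f, p = min(p, 1))
}

# flood-fill component counter (8-connectivity), queue based
oracle_count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j]) next
    k <- k + 1L
    queue <- list(c(i, j))
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      qi <- q[1]; qj <- q[2]
      if (qi < 1 || qj < 1 || qi > nrow(mask) || qj > ncol(mask)) next
      if (!mask[qi, qj] || lab[qi, qj]) next
      lab[qi, qj] <- k
      for (di in -1:1) for (dj in -1:1)
        if (di || dj) queue[[length(queue) + 1L]] <- c(qi + di, qj + dj)
    }
  }
  k
}

# render a bar of length L, width W at angle (degrees) by point-to-segment
# distance; consistent across angles so rotation tests are meaningful
render_bar <- function(L, W, angle_deg, pad = 15, phase = c(0.3, 0.3)) {
  th <- angle_deg * pi / 180
  ux <- cos(th); uy <- sin(th)
  n <- ceiling(L + 2 * pad + W)
  cx <- n / 2 + phase[1] - (L / 2) * ux
  cy <- n / 2 + phase[2] - (L / 2) * uy
  ii <- matrix(seq_len(n), n, n)          # y / row
  jj <- matrix(seq_len(n), n, n, byrow = TRUE)  # x / col
  px <- jj - cx; py <- ii - cy
  t <- pmin(pmax(px * ux + py * uy, 0), L)
  dx <- px - t * ux; dy <- py - t * uy
  sqrt(dx^2 + dy^2) <= W / 2
}

# tiny deterministic methyl/expr world for fast integration tests
small_methyl_world <- function(seed = 7, n_cpgs = 2000L, n_genes = 800L) {
  md <- generate_methylation_dataset(methyl_spec(
    n_cpgs = n_cpgs, n_genes = n_genes,
    n_promoter_island_genes = 30L, seed = seed))
  ed <- generate_expression_dataset(expr_spec(seed = seed), md$truth)
  list(md = md, ed = ed)
}
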