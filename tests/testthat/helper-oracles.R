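# Independent oracles and fixture builders shared across tests.

# Brute-force running-sum extrema: walks every position of the ranked list,
# tracking both deviations directly. Independent of the O(k) hit-position
# implementation it checks.
brute_extrema <- function(scores, is_hit, weight_exp = 1) {
  N <- length(scores)
  k <- sum(is_hit)
  w <- abs(scores)^weight_exp
  sw <- sum(w[is_hit])
  dec <- if (N == k) 0 else 1 / (N - k)
  rs <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (is_hit[i]) w[i] / sw else -dec
    if (rs > best_pos) best_pos <- rs
    if (rs < best_neg) best_neg <- rs
  }
  list(pos = best_pos, neg = best_neg)
}

# The ES the oracle predicts; at a (floating-point-level) tie between the
# two extrema either sign is admissible, so a tolerance decides.
brute_es <- function(scores, is_hit, weight_exp = 1, tol = 1e-9) {
  ex <- brute_extrema(scores, is_hit, weight_exp)
  if (ex$pos >= -ex$neg - tol) ex$pos else ex$neg
}

# TRUE when the deviation extrema are within float noise of each other, in
# which case the sign of the ES is a boundary case
brute_es_tied <- function(scores, is_hit, weight_exp = 1, tol = 1e-9) {
  ex <- brute_extrema(scores, is_hit, weight_exp)
  abs(ex$pos + ex$neg) < tol
}

# Breslow partial log-likelihood for a single covariate (no tied event
# times in the fixtures, so it coincides with coxph's Efron default).
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Upper chi-square tail for even degrees of freedom, via the closed-form
# Erlang survival function: P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!
chisq_tail_even_df <- function(x, df) {
  k <- df / 2
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins: sum of probabilities <= that of the observed
# table (with a small tolerance, as fisher.test uses).
fisher_two_sided_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small ranked signature fixture
make_signature <- function(scores, genes = NULL, method = "welch_t") {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_along(scores))
  ranked_signature(genes, scores, method = method)
}

# hand-built one-row enrichment table (for composite-rule cases)
fake_enr <- function(pathway, nes, p, mode, es = sign(nes),
                     leading_edge = c("A", "B")) {
  res <- data.frame(pathway = pathway, es = es, nes = nes, p = p,
                    size = length(leading_edge), mode = mode, n_perm = 1000,
                    stringsAsFactors = FALSE)
  res$leading_edge <- list(leading_edge)
  class(res) <- c("enrichment_table", "data.frame")
  res
}

# minimal clinical table around explicit survival data
make_clinical <- function(ids, time, event, therapy = "carboplatin-paclitaxel") {
  clinical_table(data.frame(
    sample_id = ids, therapy = therapy, time_to_event = time, event = event,
    age = 65, gender = rep(c("male", "female"), length.out = length(ids)),
    stage = "II", neoadjuvant = 0L, stringsAsFactors = FALSE))
}
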