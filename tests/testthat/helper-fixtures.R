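# Shared fixture builders and independent oracles.

# small Ct matrix with miRBase-like names
tiny_ct_matrix <- function(n_mir = 3, n_smp = 4, base = 25) {
  m <- matrix(base + seq_len(n_mir * n_smp) / 10, n_mir, n_smp,
              dimnames = list(sprintf("hsa-miR-%d-5p", seq_len(n_mir) + 90),
                              sprintf("s%d", seq_len(n_smp))))
  m
}

# expression table built through the public API from desired expression
# values; the wide-open censor limit keeps every entry detected
expr_fixture <- function(values) {
  invert_ct(ct_table(50 - values, censor_limit = 50))
}

# annotations for a one-fraction two-group cohort
two_group_ann <- function(samples, groups, fraction = "ago1") {
  data.frame(sample_id = samples, donor_id = samples, fraction = fraction,
             group = groups, input_volume_ml = 1, stringsAsFactors = FALSE)
}

# Brute-force two-sided Mann-Whitney p: enumerate U over all label
# assignments of the pooled (mid-ranked) sample; two-sided as twice the
# smaller tail, capped at 1.
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(n, n1)
  w <- colSums(matrix(r[combs], nrow = n1))
  u <- w - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u <= u_obs + 1e-9), mean(u >= u_obs - 1e-9)))
}

# AUC oracle: pairwise concordance count (Mann-Whitney U / n1 n2)
auc_pairwise <- function(scores, labels, positive = "hf") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}
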