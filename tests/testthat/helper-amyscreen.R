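# O(n^2) pair-counting AUC: mean over all positive x negative pairs of
# [score_pos > score_neg] + 1/2 [score_pos == score_neg]
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# midrank AUC used by the bootstrap oracles (kept separate from the package)
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# small two-class score fixture with controllable overlap
make_scores <- function(n_pos, n_neg, shift = 1, seed = 1) {
  set.seed(seed)
  scores <- c(rnorm(n_pos, shift), rnorm(n_neg, 0))
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  list(scores = scores, labels = labels)
}

small_spec <- function(n = 200, seed = 1, ...) {
  cohort_spec(n_participants = n, seed = seed, ...)
}
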