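# Independent oracles used across the suite. These deliberately use naive
# formulations (pair counting, tail enumeration, resampling) so they share
# no code path with the package implementations they check.

# O(n^2) pair-counting AUROC with ties counted one half
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exact two-sided McNemar p by direct binomial tail enumeration
mcnemar_enum_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  probs <- vapply(0:n, function(k) choose(n, k) * 0.5^n, numeric(1))
  sum(probs[probs <= probs[b + 1] + 1e-12])
}

# stratified (label-preserving) bootstrap of the paired AUC difference
bootstrap_auc_diff_p <- function(scores_a, scores_b, labels, reps = 1e5, seed = 1) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  set.seed(seed)
  # rank-based AUC per replicate, vectorised over replicates
  diffs <- vapply(seq_len(reps), function(r) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    lab <- labels[i]
    fast_auc(scores_a[i], lab) - fast_auc(scores_b[i], lab)
  }, numeric(1))
  2 * min(mean(diffs <= 0), mean(diffs >= 0))
}

fast_auc <- function(s, lab) {
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  r <- rank(s, ties.method = "average")
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Beer-Lambert image synthesised from two known stain vectors. The
# concentration distribution mimics H&E tissue: mostly sparse (many pixels
# dominated by one stain) with a mixed fraction.
synth_stain_image <- function(n = 4000, seed = 1,
                              h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11),
                              h_trim = 20, w_trim = NULL) {
  h <- h / sqrt(sum(h^2)); e <- e / sqrt(sum(e^2))
  set.seed(seed)
  kind <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  # mixtures skew eosin-heavy: eosin's red-channel OD is weak, so only
  # high-eosin/low-hematoxylin mixtures survive the foreground OD threshold
  # and anchor the eosin extreme of the angle distribution
  ch <- ifelse(kind == 1, runif(n, 0.3, 1.2), ifelse(kind == 2, 0, runif(n, 0.02, 0.6)))
  ce <- ifelse(kind == 2, runif(n, 0.3, 1.2), ifelse(kind == 1, 0, runif(n, 0.3, 1.5)))
  od <- cbind(ch, ce) %*% rbind(h, e)
  w <- if (is.null(w_trim)) n / h_trim else w_trim
  img <- hawkshead:::pixmat_to_image(od_to_rgb(od), h_trim, w)
  list(img = img, h = h, e = e, ch = ch, ce = ce)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# small constant-colour image
const_image <- function(rgb, h = 32, w = 32) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# quick synthetic cohort shared by several tests
tiny_cohort <- function(n = 2, tiles = 3, seed = 7, noise_sd = 0, ...) {
  generate_cohort(n, tiles, seed = seed, noise_sd = noise_sd, ...)
}

# random prediction frames for paired-test checks
random_preds <- function(n, seed, score_fn = function(lab) runif(length(lab))) {
  set.seed(seed)
  lab <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
  while (length(unique(lab)) < 2) lab <- sample(0:1, n, replace = TRUE)
  data.frame(
    tile_id = sprintf("t%03d", seq_len(n)),
    slide_id = "s1",
    x_origin = (seq_len(n) - 1L) * 512L,
    y_origin = 0L,
    score = pmin(pmax(score_fn(lab), 0), 1),
    label = lab,
    stringsAsFactors = FALSE
  )
}
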