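# Small in-code fixtures shared across test files.

# A balanced two-bio x two-tech replicate table for three variants with
# per-cell controls, built so the normalized values are known exactly.
tiny_replicates <- function() {
  cells <- expand.grid(bio_rep = 1:2, tech_rep = 1:2)
  ev <- c(10, 20, 30, 40)
  wt <- c(110, 220, 330, 440)
  truth <- c(a = 0.2, b = 0.6, c = 1.1)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      variant_id = c(names(truth), "EV", "WT", "KD"),
      bio_rep = cells$bio_rep[i], tech_rep = cells$tech_rep[i],
      raw_activity = c(ev[i] + (wt[i] - ev[i]) * truth,
                       ev[i], wt[i], ev[i] + (wt[i] - ev[i]) * 0.02)
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# Brute-force pairwise AUC oracle (ties credited 0.5), independent of the
# rank-based implementation.
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == "LoF"]
  neg <- scores[labels != "LoF"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Brute-force Kendall tau-b over all pairs.
tau_b_pairwise <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}
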