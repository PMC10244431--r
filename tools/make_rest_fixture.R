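## Trains the shipped rest/active discriminant on simulator-labelled nights
## and writes inst/extdata/rest_lda_synthetic.json. Run from the repo root.
library(wearstage)

feats <- list(); labs <- list()
for (s in 1:6) {
  cfg <- synth_config(n_epochs = 240, pre_bed_active_minutes = 25,
                      post_bed_active_minutes = 15, seed = 1000 + s)
  sr <- simulate_recording(cfg, include_ecg = FALSE)
  mf <- compute_motion_features(sr$recording$acc)
  E <- min(nrow(mf$values), length(sr$rest_mask$values))
  feats[[s]] <- mf$values[seq_len(E), ]
  labs[[s]] <- as.logical(sr$rest_mask$values)[seq_len(E)]
}
X <- do.call(rbind, feats)
y <- unlist(labs)
cat("epochs:", length(y), "rest fraction:", mean(y), "\n")
disc <- train_rest_discriminant(X, y)
p <- predict(disc, X)
cat("training balanced accuracy:",
    (mean(p[y] >= 0.3) + mean(p[!y] < 0.3)) / 2, "\n")
save_rest_discriminant(disc, "inst/extdata/rest_lda_synthetic.json")
cat("written\n")
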