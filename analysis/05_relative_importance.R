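#!/usr/bin/env Rscript
# Step 5: relative diagnostic importance with Bonferroni correction.
#
# All item pairs are compared on the test subset with the pooled two-sample
# z on the permutation distributions (two-tailed).  The correction family is
# all C(15,2) = 105 pairs; the hypothesis-driven subset -- the 7
# psychosocial items against the 3 selected physical items (walking
# difficulty TFI13, hand strength TFI17, physical fatigue TFI18), 21
# comparisons -- is exported separately.

suppressMessages(library(tfiperm))

SEED <- 20230513
R <- 10000
cohort <- read_cohort("results/cohort.csv")
complete <- drop_incomplete(cohort)
split <- read_split("results/split.json")
train <- complete[split$train, ]
test <- complete[split$test, ]

psychosocial <- paste0("TFI", 19:25)
physical <- c("TFI13", "TFI17", "TFI18")
m_hyp <- count_hypothesis_comparisons(psychosocial, physical)
cat(sprintf("Hypothesis-driven family: %d x %d = %d comparisons.\n",
            length(psychosocial), length(physical), m_hyp))

for (a in c("decision_tree", "random_forest", "adaboost")) {
  model <- train_model(model_config(a, seed = SEED), train)
  tab <- importance_table(model, test, R = R, seed = SEED, subset = "test")
  cm <- comparison_matrix(tab, alpha = 0.05, m = choose(15, 2))
  write.csv(cbind(model = a, cm$pairs),
            sprintf("results/comparison_%s_test.csv", a), row.names = FALSE)
  write.csv(as.data.frame(cm$delta),
            sprintf("results/comparison_%s_test_delta.csv", a))

  hyp <- cm$pairs[(cm$pairs$feature_a %in% psychosocial &
                     cm$pairs$feature_b %in% physical) |
                    (cm$pairs$feature_b %in% psychosocial &
                       cm$pairs$feature_a %in% physical), ]
  write.csv(cbind(model = a, hyp),
            sprintf("results/hypothesis_comparisons_%s.csv", a),
            row.names = FALSE)
  n_sig <- sum(hyp$significant)
  cat(sprintf(
    "%s: %d of %d psychosocial-vs-physical comparisons significant at p* <= %.4f\n",
    a, n_sig, nrow(hyp), cm$alpha_corrected))
  psych_wins <- hyp$significant & hyp$direction %in% psychosocial
  if (any(psych_wins)) {
    cat("  psychosocial item more important in:",
        paste(sprintf("%s>%s",
                      ifelse(hyp$feature_a[psych_wins] %in% psychosocial,
                             hyp$feature_a[psych_wins],
                             hyp$feature_b[psych_wins]),
                      ifelse(hyp$feature_a[psych_wins] %in% psychosocial,
                             hyp$feature_b[psych_wins],
                             hyp$feature_a[psych_wins]))[seq_len(min(6, sum(psych_wins)))],
              collapse = ", "), "\n")
  }
}
cat("Wrote comparison and hypothesis tables under results/.\n")
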