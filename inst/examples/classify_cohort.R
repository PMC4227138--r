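# Feeding backbone signatures to an off-the-shelf classifier.
#
# Backbone values are ordinary numeric features: any learner applies. This
# example compares leave-pair-out accuracy of LDA on raw genes vs. on the
# backbone features for a synthetic two-class cohort. Because the
# gene-to-backbone transform is data-independent, mapping once up front is
# equivalent to mapping inside each training fold.
#
#   Rscript classify_cohort.R [seed]

suppressPackageStartupMessages({
  library(toponpa)
  library(MASS)
})

seed <- if (length(commandArgs(TRUE)) >= 1)
  as.integer(commandArgs(TRUE)[[1]]) else 1

study <- simulate_study(n_backbone = 12, edge_p = 0.3, p_neg = 0.3,
                        genes_per_node = c(10, 15), p_no_genes = 0,
                        effect = 0.3, noise_sd = 1, cohort = TRUE,
                        n_per_class = 25, seed = seed)
net <- normalize_downstream_weights(study$network)
sys <- build_laplacians(net)
x <- study$cohort$x
y <- factor(study$cohort$labels$class)
n <- ncol(x)

cv_accuracy <- function(features) {
  hits <- vapply(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    fit <- lda(t(features[, train, drop = FALSE]), grouping = y[train])
    predict(fit, t(features[, i, drop = FALSE]))$class == y[i]
  }, logical(1))
  mean(hits)
}

b <- map_samples_to_backbone(sys, center_expression(x))$values
cat(sprintf("genes:    %4d features, LOO accuracy %.2f\n",
            nrow(x), cv_accuracy(x)))
cat(sprintf("backbone: %4d features, LOO accuracy %.2f\n",
            nrow(b), cv_accuracy(b)))
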