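#!/usr/bin/env Rscript
# Stage 5 — process-parameter associations and marker discovery.
#
# Spearman correlations of the 1%-filtered order profiles against the
# numeric process parameters (dual alpha 0.05/0.01), a signed
# correlation network exported as GEXF + edge list, and CART decision
# trees proposing marker metaproteins for high TAN (threshold 4200
# mg/L), thermophilic temperature (> 40 degC) and high OLR (median),
# each with a stratified 60/40 train/test split.

suppressPackageStartupMessages(library(proteotypeR))

run <- "results/run"
seed <- 1L
fl_ord <- read_matrix(file.path(run, "abundance_order_filtered.tsv"))
fl_mp <- read_matrix(file.path(run, "abundance_metaprotein_filtered.tsv"))
params <- read_parameter_table(file.path(run, "parameters.tsv"))
gt <- jsonlite::read_json(file.path(run, "ground_truth.json"),
                          simplifyVector = TRUE)

screen <- correlation_screen(fl_ord, params)
screen$rho <- signif(screen$rho, 6); screen$p_value <- signif(screen$p_value, 6)
screen$p_adjusted <- signif(screen$p_adjusted, 6)
write.table(screen, file.path(run, "correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("correlation screen: %d pairs, %d significant at 0.05, %d at 0.01\n",
            nrow(screen), sum(screen$significant_at != "none"),
            sum(screen$significant_at == "0.01")))

net <- build_network(screen, alpha = 0.05)
export_network_gexf(net, file.path(run, "network.gexf"),
                    file.path(run, "network.edges.tsv"))
cat(sprintf("network: %d nodes, %d edges (%d positive, %d negative)\n",
            nrow(net$nodes), nrow(net$edges),
            sum(net$edges$sign > 0), sum(net$edges$sign < 0)))

# planted associations, checked on the metaprotein profiles
planted <- gt$planted
sm <- match(colnames(fl_mp), params$sample_id)
for (j in seq_len(nrow(planted))) {
  f <- planted$feature[j]
  sp <- spearman(fl_mp[f, ], params[[planted$parameter[j]]][sm])
  cat(sprintf("planted %s ~ %s: rho = %.3f (p = %.2g), planted sign %+d\n",
              f, planted$parameter[j], sp$rho, sp$p_value, planted$sign[j]))
}

X <- t(fl_mp)
thr <- c(default_thresholds(), list(OLR = "median"))
rows <- list()
for (pname in names(thr)) {
  labs <- binarize_parameter(params[[pname]][match(rownames(X),
                                                   params$sample_id)],
                             thr[[pname]])
  res <- train_test_marker(X, labs, seed = seed + match(pname, names(thr)))
  cat(sprintf("marker for high %s (> %.4g, %s): %s; train/test error %.2f/%.2f\n",
              pname, attr(labs, "threshold"), attr(labs, "threshold_source"),
              res$marker, res$train_error, res$test_error))
  rows[[pname]] <- data.frame(parameter = pname, marker = res$marker,
                              threshold = attr(labs, "threshold"),
                              threshold_source = attr(labs, "threshold_source"),
                              train_error = res$train_error,
                              test_error = res$test_error,
                              stringsAsFactors = FALSE)
}
write.table(do.call(rbind, rows), file.path(run, "markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("planted high-TAN marker was %s\n", gt$marker$feature))
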