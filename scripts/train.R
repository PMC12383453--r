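#!/usr/bin/env Rscript
# Train a GPR regressor from a feature CSV and a QA CSV:
#   Rscript scripts/train.R --features features.csv --qa qa.csv \
#     --out model.json [--n-iter 50] [--seed 1]
suppressMessages({ library(optparse); library(arcqa) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--features", type = "character"),
  make_option("--qa", type = "character", default = NULL),
  make_option("--out", type = "character", default = "model.json"),
  make_option("--n-iter", type = "integer", default = 50L, dest = "n_iter"),
  make_option("--seed", type = "integer", default = 1L)
)))
tab <- read_feature_table(opts$features)
if (!is.null(opts$qa)) {
  qa <- utils::read.csv(opts$qa, stringsAsFactors = FALSE)
  tab$measured_gpr <- qa$measured_gpr[match(tab$arc_id, qa$arc_id)]
}
sel <- select_representatives(ward_clusters(spearman_matrix(tab)),
                              spearman_matrix(tab))
sp <- hybrid_split(tab, seed = opts$seed)
search <- randomized_search(tab[sp$train, ], sel, n_iter = opts$n_iter,
                            seed = opts$seed)
fit <- train_model(tab[sp$train, ], search$best_params, sel,
                   seed = opts$seed)
cal <- calibrate_threshold(predict_gpr(fit, tab[sp$validation, ]),
                           tab$measured_gpr[sp$validation])
fit$tl <- cal$tl
save_model_bundle(fit, opts$out)
cat("CV MAE:", round(search$cv_mae, 3), "+/-", round(search$cv_mae_sd, 3),
    "  TL:", round(cal$tl, 2),
    if (cal$feasible) "(feasible)" else "(infeasible)", "\n")
cat("model written to", opts$out, "\n")
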