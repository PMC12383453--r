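#!/usr/bin/env Rscript
# Evaluate a saved model bundle on a feature/QA table:
#   Rscript scripts/evaluate.R --bundle model.json --features test.csv \
#     [--qa qa.csv] [--out report.json]
suppressMessages({ library(optparse); library(arcqa) })
opts <- parse_args(OptionParser(option_list = list(
  make_option("--bundle", type = "character"),
  make_option("--features", type = "character"),
  make_option("--qa", type = "character", default = NULL),
  make_option("--out", type = "character", default = NULL)
)))
fit <- load_model_bundle(opts$bundle)
tab <- read_feature_table(opts$features)
if (!is.null(opts$qa)) {
  qa <- utils::read.csv(opts$qa, stringsAsFactors = FALSE)
  tab$measured_gpr <- qa$measured_gpr[match(tab$arc_id, qa$arc_id)]
}
rep <- evaluation_report(fit, tab)
cat("n:", rep$n, " MAE:", round(rep$regression$mae, 3),
    " R2:", round(rep$regression$r2, 3),
    " AUC:", round(rep$curves$auc, 3), "\n")
cat("at TL", rep$tl, ":",
    paste(names(rep$classification), round(rep$classification, 3),
          collapse = "  "), "\n")
if (!is.null(opts$out)) {
  out <- list(n = rep$n, tl = rep$tl,
              regression = rep$regression[c("mae", "r2")],
              classification = as.list(rep$classification),
              auc = rep$curves$auc, ap = rep$curves$ap)
  jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA)
  cat("report written to", opts$out, "\n")
}
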