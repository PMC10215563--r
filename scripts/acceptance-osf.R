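#!/usr/bin/env Rscript
# Optional reproduction suite for the deposited study data (not run by
# default: requires a manual download and a column mapping for the deposited
# layout). Given a probe-level CSV export, refits the condition, appraisal
# and follow-up analyses and prints the coefficient tables with 95% CIs,
# standardized betas and marginal/conditional R^2 for comparison with the
# published values.
#
# Usage:
#   Rscript scripts/acceptance-osf.R --probes <csv> [--mapping <yaml>]
#
# The mapping YAML holds two blocks:
#   columns:  participant: <ext col>, pressure: ..., feedback: ...,
#             pof: ..., cof: ..., anxiety: ...   (block/trial optional)
#   levels:   pressure: {<ext label>: high, <ext label>: low}, feedback: {...}
# Omitting --mapping assumes the package's own column names and labels.

suppressMessages(library(interceptvr))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(probes = NULL, mapping = NULL)
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--probes") { opt$probes <- args[i + 1L]; i <- i + 2L }
  else if (args[i] == "--mapping") { opt$mapping <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}
if (is.null(opt$probes))
  stop("--probes <csv> is required (see the file header for the format)")

if (is.null(opt$mapping)) {
  probes <- utils::read.csv(opt$probes, comment.char = "#")
} else {
  mp <- yaml::read_yaml(opt$mapping)
  probes <- read_external_probes(opt$probes, unlist(mp$columns),
                                 levels = lapply(mp$levels, unlist))
}

grp <- paste(probes$pressure, probes$feedback)
for (v in c("pof", "cof", "anxiety")) probes[[v]] <- winsorize(probes[[v]], grp)

for (out in c("pof", "cof", "anxiety")) {
  cat("\n==== condition model:", out, "====\n")
  print(fit_condition_model(probes, out))
}
cat("\n==== appraisal model: anxiety ~ pof * cof ====\n")
print(fit_appraisal_model(probes))

cat("\n==== follow-up pressure contrasts on COF (Holm) ====\n")
print(holm_followups(probes, "cof", list(
  list(factor = "pressure", within = c(feedback = "low")),
  list(factor = "pressure", within = c(feedback = "high")))))
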