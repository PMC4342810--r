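#!/usr/bin/env Rscript
# Thin command-line wrapper over the cnconcord package.
#
#   Rscript scripts/concord.R agree --channel cn|loh --build build.tsv \
#       --out result.json a.seg b.seg c.seg
#   Rscript scripts/concord.R report --manifest manifest.tsv \
#       --build build.tsv --out report.json [--panel panel.tsv] \
#       [--genes genes.bed] [--scores scores.tsv]
#   Rscript scripts/concord.R simulate --out dir [--seed 1] [--samples 3]

suppressPackageStartupMessages({
  library(optparse)
  library(cnconcord)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: concord.R <agree|report|simulate> [options]", call. = FALSE)
}
cmd <- args[1]

run <- function() {
  if (cmd == "agree") {
    opt <- parse_args(OptionParser(option_list = list(
      make_option("--channel", default = "cn"),
      make_option("--build", type = "character"),
      make_option("--out", default = "agreement.json")
    )), args = args[-1], positional_arguments = TRUE)
    build <- read_genome_build(opt$options$build)
    profiles <- lapply(opt$args, read_seg_profile, build = build)
    for (i in seq_along(profiles)) profiles[[i]]$lab <- paste0("Lab", i)
    res <- gw_call_agreement(profiles, toupper(opt$options$channel))
    jsonlite::write_json(list(channel = res$channel,
                              percentage = res$percentage,
                              agreeing_bp = res$agreeing_bp,
                              denominator_bp = res$denominator_bp,
                              disagreement = res$intervals[
                                !res$intervals$agree,
                                c("chrom", "start", "end")]),
                         opt$options$out, auto_unbox = TRUE, digits = NA)
    message("genome-wide ", res$channel, " agreement: ",
            sprintf("%.2f%%", res$percentage))
  } else if (cmd == "report") {
    opt <- parse_args(OptionParser(option_list = list(
      make_option("--manifest", type = "character"),
      make_option("--build", type = "character"),
      make_option("--panel", type = "character", default = NULL),
      make_option("--genes", type = "character", default = NULL),
      make_option("--scores", type = "character", default = NULL),
      make_option("--truth", type = "character", default = NULL),
      make_option("--out", default = "report.json")
    )), args = args[-1])
    build <- read_genome_build(opt$build)
    scores <- if (!is.null(opt$scores)) read_sm_scores(opt$scores)
    trips <- assemble_triplicates(read_manifest(opt$manifest), build,
                                  scores = scores)
    rep <- run_full_analysis(
      trips,
      panel = if (!is.null(opt$panel)) read_sm_panel(opt$panel),
      truth = if (!is.null(opt$truth)) read_sm_truth(opt$truth),
      genes = if (!is.null(opt$genes)) read_gene_bed(opt$genes))
    write_report(rep, opt$out, "json")
    print(rep)
  } else if (cmd == "simulate") {
    opt <- parse_args(OptionParser(option_list = list(
      make_option("--out", default = "simulated"),
      make_option("--seed", type = "integer", default = 1L),
      make_option("--samples", type = "integer", default = 3L)
    )), args = args[-1])
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    panel <- read_sm_panel()
    sim <- simulate_cohort(sim_config(n_samples = opt$samples,
                                      seed = opt$seed), panel = panel)
    rows <- list()
    for (t in sim$triplicates) {
      for (r in t$runs) {
        seg_path <- file.path(opt$out,
                              paste0(r$sample, "_", r$lab, ".seg"))
        write_seg_profile(r$profile, seg_path)
        rows[[length(rows) + 1]] <- data.frame(
          sample = r$sample, lab = r$lab, seg_path = seg_path,
          mapd = r$qc$mapd, ndsnpqc = r$qc$ndsnpqc,
          ploidy = r$tuscan$ploidy, acf = r$tuscan$acf)
      }
    }
    write.table(do.call(rbind, rows), file.path(opt$out, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$truth, file.path(opt$out, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    message("wrote ", length(sim$triplicates), " triplicates to ", opt$out)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
}

tryCatch(run(), error = function(e) {
  message("error: ", conditionMessage(e))
  quit(status = 2)
})
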