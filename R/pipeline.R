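#' Default pipeline configuration
#'
#' Every stage parameter carries its conventional default, so a config needs
#' to name only the inputs and an output directory. The structure
#' serialises losslessly to YAML and back.
#'
#' @param ped_path,map_path PED/MAP genotype input (or `bed/bim/fam_path`).
#' @param bed_path,bim_path,fam_path PLINK binary input (alternative).
#' @param pedigree_path optional pedigree CSV/TSV (`id,sire,dam,breed`).
#' @param linkage_map_path optional linkage map TSV (`snp_id,chrom,cM`).
#' @param out_dir output directory.
#' @param seed RNG seed for any stochastic step.
#' @param qc,roh,ne named lists overriding [qc_params()], [roh_params()],
#'   [ne_params()] fields.
#' @param fst_top_call,fst_top_extend signature-calling tail fractions.
#' @param autosome_length_bp F_ROH denominator override (`NULL`: map span).
#' @param min_cge pedigree-depth restriction for the inbreeding report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ped_path = NULL, map_path = NULL, bed_path = NULL,
                       bim_path = NULL, fam_path = NULL,
                       pedigree_path = NULL, linkage_map_path = NULL,
                       out_dir = tempfile("divscan_run"), seed = 1L,
                       qc = list(), roh = list(), ne = list(),
                       fst_top_call = 0.001, fst_top_extend = 0.05,
                       autosome_length_bp = NULL, min_cge = 6) {
  structure(list(ped_path = ped_path, map_path = map_path,
                 bed_path = bed_path, bim_path = bim_path,
                 fam_path = fam_path, pedigree_path = pedigree_path,
                 linkage_map_path = linkage_map_path, out_dir = out_dir,
                 seed = as.integer(seed), qc = qc, roh = roh, ne = ne,
                 fst_top_call = fst_top_call,
                 fst_top_extend = fst_top_extend,
                 autosome_length_bp = autosome_length_bp,
                 min_cge = min_cge),
            class = "run_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file with [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a pipeline config to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes QC, ROH detection and summaries, inbreeding coefficients,
#' global and pairwise F_ST with signature calling, and per-breed Ne
#' trajectories, writing one TSV per result under `out_dir` and a
#' `manifest.json` recording the config, stage row counts and any stage
#' failure. Stages lacking their inputs (e.g. pedigree measures without a
#' pedigree) are skipped and noted; identical config and seed reproduce
#' identical outputs.
#'
#' @param config a [run_config()] (or YAML path).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("qc", "roh", "inbreeding", "fst", "ne", "report"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  manifest <- list(config = config[!vapply(config, is.null, logical(1))],
                   version = as.character(utils::packageVersion("divscan")),
                   stages = list(), status = "running")
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  on.exit(finish())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- sprintf("failed at %s: %s", name,
                                  conditionMessage(res))
      finish()
      stop(res)
    }
    res
  }

  cohort <- stage("input", {
    if (!is.null(config$ped_path))
      read_plink_text(config$ped_path, config$map_path)
    else read_plink_binary(config$bed_path, config$bim_path, config$fam_path)
  })
  if (!is.null(config$pedigree_path))
    cohort$pedigree <- read_pedigree(config$pedigree_path)
  if (!is.null(config$linkage_map_path))
    cohort <- attach_linkage_map(
      cohort, utils::read.table(config$linkage_map_path, header = TRUE,
                                stringsAsFactors = FALSE))
  manifest$stages$input <- list(individuals = nrow(cohort$calls),
                                snps = ncol(cohort$calls))

  qcp <- do.call(qc_params, config$qc)
  qc_res <- stage("qc", run_qc(cohort, qcp))
  cohort <- qc_res$cohort
  write_tsv(qc_res$report, file.path(config$out_dir, "qc", "qc_report.tsv"))
  manifest$stages$qc <- list(individuals = nrow(cohort$calls),
                             snps = ncol(cohort$calls))

  roh_over <- config$roh
  if (is.null(roh_over$min_snps))
    roh_over$min_snps <- lencz_min_snps(ncol(cohort$calls),
                                        nrow(cohort$calls),
                                        mean_het = mean_snp_heterozygosity(cohort))
  rp <- do.call(roh_params, roh_over)
  segments <- stage("roh", scan_roh(cohort, rp))
  incidence <- snp_roh_incidence(segments, cohort)
  hotspots <- call_hotspots(incidence, cohort = cohort)
  classes <- summarize_length_classes(segments, cohort)
  chrfrac <- chromosome_roh_fraction(segments, cohort)
  tm <- tmrca_bins(segments, cohort)
  for (nm in c("segments", "incidence", "hotspots", "classes", "chrfrac"))
    write_tsv(get(nm), file.path(config$out_dir, "roh",
                                 paste0(nm, ".tsv")))
  write_tsv(tm$table, file.path(config$out_dir, "roh", "tmrca.tsv"))
  manifest$stages$roh <- list(segments = nrow(segments),
                              hotspots = nrow(hotspots))

  records <- stage("inbreeding",
                   inbreeding_records(cohort, segments,
                                      config$autosome_length_bp))
  write_tsv(records, file.path(config$out_dir, "inbreeding", "records.tsv"))
  if (!is.null(cohort$pedigree) &&
        sum(records$cge >= config$min_cge, na.rm = TRUE) >= 3) {
    rep_ib <- inbreeding_report(records, config$min_cge)
    write_tsv(rep_ib$correlations,
              file.path(config$out_dir, "inbreeding", "correlations.tsv"))
    write_tsv(rep_ib$regressions,
              file.path(config$out_dir, "inbreeding", "regressions.tsv"))
    manifest$stages$inbreeding <- list(records = nrow(records))
  } else {
    manifest$stages$inbreeding <-
      list(records = nrow(records),
           note = "pedigree measures skipped (no/too-shallow pedigree)")
  }

  if (length(unique(cohort$individuals$breed)) >= 2) {
    fst <- stage("fst", {
      rec <- window_average(wc_theta(cohort))
      sig <- call_signatures(rec, config$fst_top_call, config$fst_top_extend)
      pw <- if (length(unique(cohort$individuals$breed)) > 2)
        pairwise_fst(cohort)$mean_fst else NULL
      list(rec = rec, sig = sig, pw = pw)
    })
    write_tsv(fst$rec, file.path(config$out_dir, "fst", "per_snp.tsv"))
    write_tsv(fst$sig, file.path(config$out_dir, "fst", "signatures.tsv"))
    if (!is.null(fst$pw))
      write_tsv(fst$pw, file.path(config$out_dir, "fst", "pairwise_mean.tsv"))
    manifest$stages$fst <- list(mean_genomic_fst = mean_genomic_fst(fst$rec),
                                signatures = nrow(fst$sig))
  } else {
    manifest$stages$fst <- list(note = "skipped: fewer than 2 breeds")
  }

  nep <- do.call(ne_params, config$ne)
  ne_tabs <- list()
  for (b in unique(cohort$individuals$breed)) {
    tab <- tryCatch(ne_trajectory(cohort, b, nep), error = function(e) NULL)
    if (!is.null(tab)) {
      ne_tabs[[b]] <- tab
      write_tsv(tab, file.path(config$out_dir, "ne",
                               paste0("ne_", b, ".tsv")))
    }
  }
  manifest$stages$ne <- list(breeds_estimated = length(ne_tabs))

  make_report(config$out_dir)
  manifest$status <- "ok"
  invisible(manifest)
}

read_tsv_if <- function(path) {
  if (file.exists(path))
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
}

fmt_section <- function(title, df) {
  c(title, strrep("-", nchar(title)),
    if (is.null(df)) "(not computed in this run)" else
      if (nrow(df) == 0) "(no rows)" else
        utils::capture.output(print(df, row.names = FALSE)), "")
}

#' Assemble a plain-text summary report
#'
#' Collects the pipeline's output tables into one human-readable document
#' with five sections: ROH length classes, inbreeding correlations, ROH
#' hotspots, selection signatures and Ne trajectories. Missing sections
#' get a placeholder rather than an error.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return The report path, invisibly.
#' @export
make_report <- function(out_dir) {
  ne_files <- list.files(file.path(out_dir, "ne"), full.names = TRUE,
                         pattern = "^ne_.*\\.tsv$")
  ne_tab <- if (length(ne_files))
    do.call(rbind, lapply(ne_files, function(f) {
      d <- read_tsv_if(f)
      d$breed <- sub("^ne_(.*)\\.tsv$", "\\1", basename(f))
      d
    })) else NULL
  lines <- c(
    "divscan pipeline report", "=======================", "",
    fmt_section("Mean ROH sum per animal by length class (Mb)",
                read_tsv_if(file.path(out_dir, "roh", "classes.tsv"))),
    fmt_section("Inbreeding coefficient correlations (CGE-restricted)",
                read_tsv_if(file.path(out_dir, "inbreeding",
                                      "correlations.tsv"))),
    fmt_section("ROH hotspots (top-1% incidence)",
                read_tsv_if(file.path(out_dir, "roh", "hotspots.tsv"))),
    fmt_section("Selection signatures (top 0.1% windowed F_ST)",
                read_tsv_if(file.path(out_dir, "fst", "signatures.tsv"))),
    fmt_section("Effective population size trajectories", ne_tab))
  path <- file.path(out_dir, "report", "report.txt")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}
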