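# End-to-end orchestration: one call reads the gene matrix and abundance
# (or coverage) table, computes the niche space, the overlap and dynamics
# series, and the overlap-vs-change regressions, and writes every result
# plus a run manifest to an output directory.

#' Run the niche-overlap analysis pipeline
#'
#' Stages: read and validate inputs; pairwise Jaccard distances; PCoA niche
#' space; per-time-point detection and the three overlap indices;
#' community-dynamics series (consecutive beta-diversity, abruptness where
#' the series is dense, Shannon alpha-diversity, rescaled copies); OLS
#' regressions of lagged beta-diversity and of alpha-diversity on each
#' overlap index. All outputs are written as TSV/JSON into \code{out_dir}
#' together with a manifest (configuration echo, package version, input
#' checksums). Deterministic given the inputs.
#'
#' @param gene_matrix path to the MAG x gene TSV.
#' @param abundance_table path to the day x MAG relative-abundance TSV
#'   (mutually exclusive with \code{coverage_table}).
#' @param coverage_table path to a long-format coverage TSV, converted to
#'   relative abundance via RPKM normalization.
#' @param out_dir output directory (created if needed).
#' @param detection_threshold relative-abundance detection threshold.
#' @param n_axes PCoA axes to report.
#' @param window_size abruptness window in days.
#' @param weight_normalization weight convention for the weighted index.
#' @param normalize_abundance close abundance rows to the simplex on read.
#' @param format input table dialect, \code{"tsv"} or \code{"csv"}.
#' @return invisibly, a list with all computed objects (\code{distance},
#'   \code{pcoa}, \code{overlap}, \code{dynamics}, \code{regressions},
#'   \code{paired}, \code{manifest}).
#' @export
run_overlap <- function(gene_matrix,
                        abundance_table = NULL,
                        coverage_table = NULL,
                        out_dir,
                        detection_threshold = 0.001,
                        n_axes = 3L,
                        window_size = 5L,
                        weight_normalization = c("detected_set", "global"),
                        normalize_abundance = FALSE,
                        format = "tsv") {
  weight_normalization <- match.arg(weight_normalization)
  if (is.null(abundance_table) == is.null(coverage_table)) {
    stop("provide exactly one of abundance_table or coverage_table", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genes <- stage("read gene matrix", read_gene_matrix(gene_matrix, format))
  if (!is.null(abundance_table)) {
    a <- stage("read abundance table",
               read_abundance_table(abundance_table, normalize_abundance, format))
    abundance_input <- abundance_table
  } else {
    cov <- stage("read coverage table", read_coverage_table(coverage_table, format))
    a <- stage("coverage normalization", relative_abundance_from_coverage(cov))
    abundance_input <- coverage_table
  }
  missing <- setdiff(colnames(a), rownames(genes))
  if (length(missing)) {
    stop("[match inputs] abundance MAG(s) missing from gene matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  D <- stage("pairwise Jaccard", pairwise_jaccard(genes))
  ord <- stage("PCoA", pcoa(D, n_axes = n_axes))
  ov <- stage("overlap series",
              overlap_series(D, a, threshold = detection_threshold,
                             weight_normalization = weight_normalization))
  if (all(is.na(ov$overall_mean))) {
    warning("all overlap scores are undefined (fewer than 2 MAGs detected ",
            "at every time point); check detection_threshold", call. = FALSE)
  }
  dyn <- stage("dynamics series", dynamics_series(a, window = window_size))

  regressions <- list()
  for (idx in c("overall_mean", "nearest_mean", "weighted_nearest_mean")) {
    regressions[[idx]] <- list(
      beta_next = try_regression(ov[[idx]][-nrow(ov)], dyn$beta_next[-nrow(dyn)]),
      alpha = try_regression(ov[[idx]], dyn$alpha))
  }
  paired <- tryCatch(pair_overlap_with_change(ov, dyn), error = function(e) NULL)

  write_square(D, file.path(out_dir, "jaccard_distance.tsv"))
  coords <- ord$coordinates
  write_with_id(coords, file.path(out_dir, "pcoa_coordinates.tsv"),
                id_name = "mag_id", sep = "\t")
  jsonlite::write_json(
    list(eigenvalues = ord$eigenvalues,
         proportion_explained = ord$proportion_explained,
         n_negative_eigenvalues = ord$n_negative_eigenvalues),
    file.path(out_dir, "pcoa_eigenvalues.json"),
    auto_unbox = TRUE, digits = NA)
  write_series(ov, file.path(out_dir, "overlap_series.tsv"))
  write_series(dyn, file.path(out_dir, "dynamics_series.tsv"))
  if (!is.null(paired) && nrow(paired) > 0) {
    write_series(paired, file.path(out_dir, "overlap_vs_change.tsv"))
  }
  jsonlite::write_json(serialize_regressions(regressions),
                       file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- list(
    package = "nichespace",
    version = as.character(utils::packageVersion("nichespace")),
    config = list(detection_threshold = detection_threshold,
                  n_axes = n_axes, window_size = window_size,
                  weight_normalization = weight_normalization,
                  normalize_abundance = normalize_abundance,
                  format = format),
    inputs = list(gene_matrix = input_checksum(gene_matrix),
                  abundance = input_checksum(abundance_input)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(distance = D, pcoa = ord, overlap = ov, dynamics = dyn,
                 regressions = regressions, paired = paired,
                 manifest = manifest))
}

#' Generate and write a synthetic scenario bundle
#'
#' Writes the guild-structured gene matrix, the daily abundance table, the
#' sparse sampled table, and a truth file (guild assignments, measured
#' collapse day, configuration echo) into \code{out_dir}.
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, the [generate_scenario()] list.
#' @export
run_synthetic <- function(cfg = scenario_config(), seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- stage("scenario generation", generate_scenario(cfg, seed))
  write_gene_matrix(sc$genomes, file.path(out_dir, "genomes.tsv"))
  write_abundance_table(sc$daily, file.path(out_dir, "abundance_daily.tsv"))
  write_abundance_table(sc$sampled, file.path(out_dir, "abundance_sampled.tsv"))
  jsonlite::write_json(
    list(seed = seed,
         guild = as.list(sc$guild),
         collapse_day = sc$collapse_day,
         max_abruptness = sc$max_abruptness,
         config = unclass(sc$config)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

# run a stage, prefixing any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

try_regression <- function(x, y) {
  tryCatch(overlap_regression(x, y), error = function(e) {
    structure(list(error = conditionMessage(e)), class = "failed_regression")
  })
}

serialize_regressions <- function(regressions) {
  lapply(regressions, function(per_response) {
    lapply(per_response, function(r) {
      if (inherits(r, "failed_regression")) return(list(error = r$error))
      r$band <- NULL
      unclass(r)
    })
  })
}

write_square <- function(D, path) {
  write_with_id(D, path, id_name = "id", sep = "\t")
}

input_checksum <- function(path) {
  list(path = path, md5 = unname(tools::md5sum(path)))
}
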