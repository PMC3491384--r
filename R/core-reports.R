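# Canonical (possibly empty) report tables and their column sets.
.REPORT_TABLES <- list(
  spacers = c("array_id", "spacer_index", "contig_id", "start", "end",
              "strand", "read_count", "relative_abundance", "five_tag_length",
              "five_tag_sequence", "three_modal_offset", "trimming_hotspots",
              "flags"),
  termini = c("contig_id", "position", "strand", "side", "support",
              "local_fraction", "is_hotspot", "is_modal", "region_id"),
  trna_pairs = c("five_id", "three_id", "duplex_len", "duplex_score",
                 "gc_fraction_of_duplex", "ambiguous", "junction",
                 "mature_len", "mature_seq"),
  leaderless = c("feature_id", "mature_start_fraction", "start_base",
                 "purine_start", "minus1_fraction", "minus1_base"),
  cd_srnas = c("srna_id", "contig_id", "start", "end", "strand",
               "arrangement", "context", "boxC_seq", "boxD_seq", "boxCp_seq",
               "boxDp_seq", "score", "terminal_pairing",
               "junction_read_support", "circular"),
  haca_srnas = c("srna_id", "contig_id", "start", "end", "strand",
                 "n_hairpins", "hinge_pos", "terminal_ACA", "h_domain_status",
                 "kturn_flags"),
  targets = c("srna_id", "guide_source", "target_rna", "target_position",
              "duplex_len", "n_gu", "modification")
)

empty_report_table <- function(name) {
  cols <- .REPORT_TABLES[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Write pipeline reports
#'
#' Emits one GFF3 of all called features, one TSV per feature class and a
#' JSON run summary, all with deterministic field order; running twice on the
#' same results gives byte-identical files.
#'
#' @param results list with any of: `features` (feature table), `genome`
#'   (list of genome records), the report tables named in the package
#'   (`spacers`, `termini`, `trna_pairs`, `leaderless`, `cd_srnas`,
#'   `haca_srnas`, `targets`) and `summary` (a list).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_reports <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop_fmt("cannot write to output directory: %s", out_dir)
  }
  written <- character(0)

  feats <- results$features %||% feature_table()
  gff <- file.path(out_dir, "features.gff3")
  write_gff3(feats, gff, contigs = results$genome)
  written <- c(written, gff)

  for (nm in names(.REPORT_TABLES)) {
    df <- results[[nm]]
    if (is.null(df) || nrow(df) == 0) {
      df <- empty_report_table(nm)
    } else {
      miss <- setdiff(.REPORT_TABLES[[nm]], colnames(df))
      for (m in miss) df[[m]] <- NA
      df <- df[, .REPORT_TABLES[[nm]], drop = FALSE]
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    written <- c(written, path)
  }

  summ <- results$summary %||% list()
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  written <- c(written, path)
  invisible(written)
}
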