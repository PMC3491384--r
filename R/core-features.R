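# Feature kinds recognised by the pipeline and their GFF3 type names.
.KIND_TYPES <- c(
  gene = "gene", tRNA = "tRNA", tRNA_half = "tRNA_half", rRNA = "rRNA",
  CRISPR_array = "CRISPR_array", CD_sRNA = "CD_sRNA", HACA_sRNA = "HACA_sRNA",
  leader = "leader", other = "region"
)

.TYPE_KINDS <- c(
  gene = "gene", mRNA = "gene", CDS = "gene",
  tRNA = "tRNA", tRNA_half = "tRNA_half",
  rRNA = "rRNA",
  CRISPR_array = "CRISPR_array", repeat_region = "CRISPR_array",
  CD_sRNA = "CD_sRNA", HACA_sRNA = "HACA_sRNA",
  leader = "leader"
)

#' Build a feature table
#'
#' Features use 0-based half-open forward-strand intervals.  `attrs` holds
#' free-form key=value metadata as a single semicolon-joined string.
#'
#' @param feature_id,contig_id character vectors.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand "+", "-" or NA (undefined, e.g. an unoriented CRISPR array).
#' @param kind one of gene, tRNA, tRNA_half, rRNA, CRISPR_array, CD_sRNA,
#'   HACA_sRNA, leader, other.
#' @param attrs character vector of "key=value;key=value" strings ("" if none).
#' @return data.frame with one row per feature.
#' @export
feature_table <- function(feature_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), kind = character(),
                          attrs = character()) {
  df <- data.frame(feature_id = as.character(feature_id),
                   contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   attrs = as.character(attrs),
                   stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(df) > 0) {
    bad <- which(df$start < 0 | df$start >= df$end)
    if (length(bad) > 0) {
      stop_fmt("invalid interval for feature '%s': start=%d end=%d",
               df$feature_id[bad[1]], df$start[bad[1]], df$end[bad[1]])
    }
    unknown <- setdiff(unique(df$kind), names(.KIND_TYPES))
    if (length(unknown) > 0) stop_fmt("unknown feature kind '%s'", unknown[1])
    badstr <- which(!(df$strand %in% c("+", "-") | is.na(df$strand)))
    if (length(badstr) > 0) {
      stop_fmt("unknown strand symbol '%s' for feature '%s'",
               df$strand[badstr[1]], df$feature_id[badstr[1]])
    }
  }
  df
}

# --- attribute helpers -------------------------------------------------------

#' Get a key=value attribute from a feature attrs string
#' @param attrs attribute string(s) as stored in a feature table.
#' @param key attribute key.
#' @return character vector (NA where absent).
#' @export
attr_get <- function(attrs, key) {
  vapply(attrs, function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_character_)
    kv <- strsplit(a, ";", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub("^[^=]*=", "", hit[1])
  }, character(1), USE.NAMES = FALSE)
}

attrs_build <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  if (length(kv) == 0) return("")
  kv <- kv[order(names(kv))]
  paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = ";")
}

# canonical (sorted-key) form of an attrs string
attrs_canonical <- function(attrs) {
  vapply(attrs, function(a) {
    if (is.na(a) || !nzchar(a)) return("")
    kv <- strsplit(a, ";", fixed = TRUE)[[1]]
    kv <- kv[nzchar(kv)]
    keys <- sub("=.*$", "", kv)
    paste(kv[order(keys)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

# --- GFF3 I/O ----------------------------------------------------------------

#' Read a GFF3 file into the internal feature table
#'
#' Coordinates are converted from GFF3 1-based inclusive to the internal
#' 0-based half-open convention.  The GFF3 `type` column maps onto feature
#' kinds (`gene`/`mRNA`/`CDS` -> gene, `tRNA`, `tRNA_half`, `rRNA`,
#' `CRISPR_array`/`repeat_region` -> CRISPR_array, `CD_sRNA`, `HACA_sRNA`,
#' `leader`); anything else becomes kind `other` and keeps its original type
#' in the `gff_type` attribute.
#'
#' @param path GFF3 file.
#' @return feature table (see [feature_table()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_fmt("GFF3 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_fmt("invalid GFF3 '%s': %s",
                                              path, conditionMessage(e)))
  n <- length(gr)
  if (n == 0) return(feature_table())
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  kind <- unname(.TYPE_KINDS[type])
  kind[is.na(kind)] <- "other"
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- NA_character_
  ids <- if ("ID" %in% colnames(mc)) as.character(mc$ID) else rep(NA, n)
  ids[is.na(ids)] <- sprintf("feature_%04d", which(is.na(ids)))
  skip <- c("source", "type", "score", "phase", "ID")
  extra <- setdiff(colnames(mc), skip)
  attrs <- vapply(seq_len(n), function(i) {
    kv <- list()
    for (k in extra) {
      v <- mc[[k]][i]
      if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) == 0 || all(is.na(v))) next
      kv[[k]] <- paste(as.character(v), collapse = ",")
    }
    if (kind[i] == "other" && !type[i] %in% names(.TYPE_KINDS)) {
      kv[["gff_type"]] <- type[i]
    }
    do.call(attrs_build, kv)
  }, character(1))
  feature_table(
    feature_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand, kind = kind, attrs = attrs
  )
}

#' Write a feature table to GFF3
#'
#' Inverse of [read_gff3()]: intervals go back to 1-based inclusive, kind maps
#' to the type column, attributes are written with sorted keys after `ID` so
#' that output is byte-deterministic.
#'
#' @param features feature table.
#' @param path output file.
#' @param contigs optional list of [genome_record()] for sequence-region
#'   headers.
#' @export
write_gff3 <- function(features, path, contigs = NULL) {
  lines <- "##gff-version 3"
  if (!is.null(contigs)) {
    if (inherits(contigs, "genome_record")) contigs <- list(contigs)
    lines <- c(lines, vapply(contigs, function(g) {
      sprintf("##sequence-region %s 1 %d", g$contig_id, g$length)
    }, character(1)))
  }
  if (nrow(features) > 0) {
    type <- ifelse(features$kind == "other",
                   ifelse(is.na(attr_get(features$attrs, "gff_type")),
                          "region", attr_get(features$attrs, "gff_type")),
                   unname(.KIND_TYPES[features$kind]))
    attrs <- attrs_canonical(features$attrs)
    # drop gff_type from the attribute column (it lives in the type column)
    attrs <- vapply(attrs, function(a) {
      kv <- strsplit(a, ";", fixed = TRUE)[[1]]
      paste(kv[!startsWith(kv, "gff_type=")], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    attrcol <- sprintf("ID=%s%s", features$feature_id,
                       ifelse(nzchar(attrs), paste0(";", attrs), ""))
    rows <- sprintf("%s\tnanosmallrna\t%s\t%d\t%d\t.\t%s\t.\t%s",
                    features$contig_id, type,
                    features$start + 1L, features$end,
                    ifelse(is.na(features$strand), ".", features$strand),
                    attrcol)
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Intergenic complement of a feature table
#'
#' @param features feature table (rows of any kind count as genic unless
#'   excluded via `exclude_kinds`).
#' @param contig_len contig length (nt).
#' @param exclude_kinds kinds ignored when building the genic mask.
#' @return data.frame of 0-based half-open intergenic intervals.
#' @export
intergenic_intervals <- function(features, contig_len,
                                 exclude_kinds = c("leader")) {
  use <- features[!(features$kind %in% exclude_kinds), , drop = FALSE]
  if (nrow(use) == 0) {
    return(data.frame(start = 0L, end = as.integer(contig_len)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(use$start + 1L, use$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = contig_len)
  data.frame(start = BiocGenerics::start(gaps) - 1L,
             end = BiocGenerics::end(gaps))
}
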