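#' Read per-sample CNV calls
#'
#' Reads a table of read-depth CNV calls in either the nine-column caller
#' dialect (`"cnvnator"`) or the package's plain TSV dialect (`"tsv"`), and
#' converts coordinates to the internal convention. Internally all intervals
#' are 0-based half-open, so `size == end - start` exactly; the caller dialect
#' uses 1-based inclusive `chrom:start-end` strings and is converted on read.
#'
#' The caller dialect has columns: type, coordinates, size, normalized read
#' depth, four e-values, and q0 (the fraction of reads with zero mapping
#' quality). Which e-value column is treated as the call p-value is selected
#' by `pval_column` (default the first).
#'
#' @param path Path to the call file. Gzip-compressed files are read
#'   transparently.
#' @param dialect `"cnvnator"` (nine columns, 1-based inclusive coordinates)
#'   or `"tsv"` (headered table already in internal coordinates).
#' @param sample_id Sample identifier attached to every call. For the
#'   `"cnvnator"` dialect (which carries no sample column) this defaults to
#'   the file name without extension; the `"tsv"` dialect carries its own
#'   `sample_id` column.
#' @param pval_column Which of the four e-value columns (1-4) to use as the
#'   call p-value in the `"cnvnator"` dialect.
#' @return A data.frame of calls with columns `sample_id`, `chrom`, `start`,
#'   `end`, `svtype` (`"DEL"`/`"DUP"`), `size`, `norm_rd`, `pval`, `q0`;
#'   coordinates 0-based half-open.
#' @seealso [write_cnv_calls()], [filter_calls()]
#' @export
read_cnv_calls <- function(path, dialect = c("cnvnator", "tsv"),
                           sample_id = NULL, pval_column = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    if (file.size(path) == 0) return(empty_calls())
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("sample_id", "chrom", "start", "end", "svtype", "size",
              "norm_rd", "pval", "q0")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    calls <- df[, need]
    calls$svtype <- check_svtype(calls$svtype, path)
    return(validate_calls(calls))
  }
  stopifnot(pval_column %in% 1:4)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_calls())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed call line(s) (fewer than 9 fields) at line ",
         paste(which(nf < 9), collapse = ", "), " of ", path)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  svtype <- parse_svtype_token(m[, 1], path)
  coord <- regmatches(m[, 2], regexec("^(.+):([0-9]+)-([0-9]+)$", m[, 2]))
  bad <- which(lengths(coord) != 4)
  if (length(bad)) {
    stop("unparseable coordinate string at line ",
         paste(bad, collapse = ", "), " of ", path, " (e.g. '",
         m[bad[1], 2], "')")
  }
  coord <- do.call(rbind, coord)
  start1 <- as.numeric(coord[, 3])  # 1-based inclusive
  end1 <- as.numeric(coord[, 4])
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(txt|tsv|out|calls)(\\.gz)?$", "", basename(path))
  }
  calls <- data.frame(
    sample_id = sample_id,
    chrom = coord[, 2],
    start = start1 - 1,          # internal 0-based half-open
    end = end1,
    svtype = svtype,
    size = end1 - start1 + 1,
    norm_rd = as.numeric(m[, 4]),
    pval = as.numeric(m[, 4 + pval_column]),
    q0 = as.numeric(m[, 9]),
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
}

#' Write CNV calls
#'
#' Inverse of [read_cnv_calls()]. In the `"cnvnator"` dialect coordinates are
#' emitted 1-based inclusive and the p-value is written to all four e-value
#' columns so the file round-trips regardless of `pval_column`; the sample
#' identifier is not part of that dialect (one file per sample). The `"tsv"`
#' dialect writes the full internal table including `sample_id`.
#'
#' @param calls Data.frame of calls as returned by [read_cnv_calls()].
#' @param path Output path; a `.gz` suffix compresses.
#' @param dialect `"cnvnator"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path, dialect = c("cnvnator", "tsv")) {
  dialect <- match.arg(dialect)
  con <- open_out(path)
  on.exit(close(con))
  if (dialect == "tsv") {
    utils::write.table(calls, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  type <- ifelse(calls$svtype == "DEL", "deletion", "duplication")
  coords <- sprintf("%s:%d-%d", calls$chrom, as.integer(calls$start) + 1L,
                    as.integer(calls$end))
  out <- paste(type, coords, format_num(calls$size), format_num(calls$norm_rd),
               format_num(calls$pval), format_num(calls$pval),
               format_num(calls$pval), format_num(calls$pval),
               format_num(calls$q0), sep = "\t")
  writeLines(out, con)
  invisible(path)
}

#' Read gene or QTL features
#'
#' Reads genomic features from GFF3 (1-based inclusive; parsed with
#' \pkg{rtracklayer}) or a BED-like table (already 0-based half-open), and
#' returns them in the internal 0-based half-open convention. The dialect is
#' chosen from the file extension unless `format` is given.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file (optionally
#'   gzip-compressed).
#' @param kind Feature kind to attach, `"gene"` or `"qtl"`.
#' @param format Override the extension-based dialect detection
#'   (`"gff3"` or `"bed"`).
#' @return A data.frame with columns `feature_id`, `kind`, `chrom`, `start`,
#'   `end`, `name`, `trait_class` (QTL trait class when present, else `NA`)
#'   and a list-column `attributes` of key/value pairs.
#' @export
read_features <- function(path, kind = c("gene", "qtl"), format = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(sub("\\.gz$", "", path))
    format <- if (grepl("\\.gff3?$", ext)) "gff3"
      else if (grepl("\\.bed$", ext)) "bed"
      else stop("cannot infer format from extension of ", path,
                "; pass format = 'gff3' or 'bed'")
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    n <- length(gr)
    if (!n) return(empty_features())
    id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, n)
    nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA, n)
    nm <- ifelse(is.na(nm) | !nzchar(nm), id, nm)
    id <- ifelse(is.na(id) | !nzchar(id), paste0(kind, "_", seq_len(n)), id)
    nm <- ifelse(is.na(nm), id, nm)
    trait <- if ("trait_class" %in% names(md)) as.character(md$trait_class)
      else rep(NA_character_, n)
    attrs <- lapply(seq_len(n), function(i) {
      v <- as.list(md[i, , drop = FALSE])
      lapply(v, function(x) if (is.atomic(x)) x else unlist(as.list(x)))
    })
    out <- data.frame(
      feature_id = id, kind = kind,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      name = nm, trait_class = trait, stringsAsFactors = FALSE
    )
    out$attributes <- attrs
  } else {
    if (file.size(path) == 0) return(empty_features())
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("BED-like table needs at least 3 columns: ", path)
    n <- nrow(df)
    nm <- if (ncol(df) >= 4) as.character(df[[4]])
      else paste0(kind, "_", seq_len(n))
    out <- data.frame(
      feature_id = nm, kind = kind, chrom = as.character(df[[1]]),
      start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
      name = nm, trait_class = NA_character_, stringsAsFactors = FALSE
    )
    out$attributes <- rep(list(list()), n)
  }
  stopifnot(all(out$start < out$end))
  out
}

#' Write CNVRs as BED5
#'
#' Emits one BED line per region: chrom, start, end (0-based half-open, the
#' native BED convention), svtype in column 4 and carrier count in column 5.
#' Input not sorted by (chrom, start) is sorted with a warning.
#'
#' @param regions CNVR data.frame from [merge_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvr_bed <- function(regions, path) {
  con <- open_out(path)
  on.exit(close(con))
  if (nrow(regions)) {
    o <- order(chrom_rank(regions$chrom), regions$start)
    if (!identical(o, seq_len(nrow(regions)))) {
      warning("regions not sorted by (chrom, start); sorting before writing")
      regions <- regions[o, ]
    }
    out <- paste(regions$chrom, format_num(regions$start),
                 format_num(regions$end), regions$svtype,
                 regions$n_carriers, sep = "\t")
    writeLines(out, con)
  }
  invisible(path)
}

#' Read/write a numeric matrix as TSV
#'
#' The TSV has a header row of sample ids and a first column (`region_id`) of
#' row identifiers; `read_matrix_tsv(write_matrix_tsv(x, p))` is the identity
#' on matrices with dimnames.
#'
#' @param values Numeric matrix with rownames and colnames.
#' @param path File path (`.gz` transparently compressed).
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  df <- data.frame(region_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- open_out(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "region_id") stop("expected first column 'region_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region_id
  storage.mode(m) <- "double"
  m
}

#' Strip the "chr" prefix for annotation matching
#'
#' Chromosome names from mixed sources are compared case-insensitively with
#' any leading "chr" removed, so `"chr1"`, `"Chr1"` and `"1"` all match.
#'
#' @param x Character vector of chromosome names.
#' @return Normalized names.
#' @export
norm_chrom <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))

# natural ordering rank for chromosome names (chr2 before chr10)
chrom_rank <- function(x) {
  key <- norm_chrom(x)
  num <- suppressWarnings(as.numeric(key))
  ord <- order(is.na(num), num, key)
  match(key, key[ord])
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

format_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         format(round(x), scientific = FALSE, trim = TRUE),
         format(x, digits = 15, trim = TRUE))
}

empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = numeric(),
             end = numeric(), svtype = character(), size = numeric(),
             norm_rd = numeric(), pval = numeric(), q0 = numeric(),
             stringsAsFactors = FALSE)
}

empty_features <- function() {
  out <- data.frame(feature_id = character(), kind = character(),
                    chrom = character(), start = numeric(), end = numeric(),
                    name = character(), trait_class = character(),
                    stringsAsFactors = FALSE)
  out$attributes <- list()
  out
}

parse_svtype_token <- function(tok, path) {
  key <- c(deletion = "DEL", duplication = "DUP", DEL = "DEL", DUP = "DUP",
           del = "DEL", dup = "DUP")
  sv <- unname(key[tok])
  bad <- which(is.na(sv))
  if (length(bad)) {
    stop("unknown svtype token '", tok[bad[1]], "' at line ",
         paste(bad, collapse = ", "), " of ", path)
  }
  sv
}

check_svtype <- function(sv, where) {
  bad <- which(!sv %in% c("DEL", "DUP"))
  if (length(bad)) {
    stop("unknown svtype '", sv[bad[1]], "' in ", where)
  }
  sv
}

validate_calls <- function(calls) {
  stopifnot(all(calls$start < calls$end),
            all(calls$size == calls$end - calls$start),
            all(calls$q0 >= 0 & calls$q0 <= 1),
            all(calls$pval >= 0 & calls$pval <= 1),
            all(calls$norm_rd >= 0))
  calls
}
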