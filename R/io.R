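# Plain-text readers/writers. All files are tab-separated; coordinates are
# written 0-based half-open (each writer states the convention in a header
# comment). Malformed lines raise errors naming the file and line number.

io_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

read_tsv_raw <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  list(lines = lines[keep], lineno = which(keep))
}

validate_intervals <- function(df, path, lineno) {
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    io_error(path, lineno[bad[1]], "start/end are not numeric")
  bad <- which(start < 0)
  if (length(bad))
    io_error(path, lineno[bad[1]], "negative start coordinate")
  bad <- which(end <= start)
  if (length(bad))
    io_error(path, lineno[bad[1]],
             sprintf("end (%s) <= start (%s)", end[bad[1]], start[bad[1]]))
  df$start <- start
  df$end <- end
  df
}

#' Read a BED-like file
#'
#' BED3 plus optional named extra columns; `#` lines are comments. Input is
#' 0-based half-open unless `one_based = TRUE`, in which case 1-based
#' inclusive coordinates are converted on the way in.
#'
#' @param path file path.
#' @param extra_cols names for columns beyond chrom/start/end (in order).
#' @param one_based input uses 1-based inclusive coordinates.
#' @return data frame with chrom, start, end and any extra columns.
#' @export
read_bed <- function(path, extra_cols = NULL, one_based = FALSE) {
  raw <- read_tsv_raw(path)
  if (!length(raw$lines))
    return(do.call(data.frame,
                   c(list(chrom = character(0), start = numeric(0),
                          end = numeric(0)),
                     setNames(rep(list(character(0)), length(extra_cols)),
                              extra_cols))))
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  ncols <- 3L + length(extra_cols)
  short <- which(lengths(parts) < ncols)
  if (length(short))
    io_error(path, raw$lineno[short[1]],
             sprintf("expected %d tab-separated fields, found %d",
                     ncols, length(parts[[short[1]]])))
  get_col <- function(i) vapply(parts, `[[`, character(1), i)
  df <- data.frame(chrom = get_col(1), start = get_col(2), end = get_col(3),
                   stringsAsFactors = FALSE)
  for (i in seq_along(extra_cols)) {
    v <- get_col(3L + i)
    num <- suppressWarnings(as.numeric(v))
    df[[extra_cols[i]]] <- if (all(!is.na(num))) num else v
  }
  if (one_based) df$start <- suppressWarnings(as.numeric(df$start)) - 1
  validate_intervals(df, path, raw$lineno)
}

#' Write a BED-like file
#'
#' @param df data frame whose first three columns are chrom, start, end.
#' @param path output path.
#' @param header extra header comment lines (without the leading `#`).
#' @export
write_bed <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based half-open",
               paste0("# ", header)[seq_along(header)]), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col)
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE)
      else as.character(col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read / write chromosome sizes (two-column TSV)
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  raw <- read_tsv_raw(path)
  parts <- strsplit(raw$lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short))
    io_error(path, raw$lineno[short[1]], "expected 2 tab-separated fields")
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad))
    io_error(path, raw$lineno[bad[1]], "chromosome length is not positive")
  setNames(len, vapply(parts, `[[`, character(1), 1))
}

#' @rdname read_chrom_sizes
#' @param sizes named numeric vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), format(sizes, scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Read / write a per-bin depth track (chrom, start, end, depth TSV)
#'
#' @param path file path.
#' @param id individual id to record on the track (defaults to the file
#'   name).
#' @param one_based input is 1-based inclusive.
#' @return a `depth_track` plus attribute `regions` with the bin
#'   coordinates.
#' @export
read_depth_tsv <- function(path, id = NULL, one_based = FALSE) {
  df <- read_bed(path, extra_cols = "depth", one_based = one_based)
  if (!is.numeric(df$depth))
    io_error(path, 1L, "depth column is not numeric")
  tr <- depth_track(id %||% sub("\\.[^.]*$", "", basename(path)), df$depth)
  attr(tr, "regions") <- df[, c("chrom", "start", "end")]
  tr
}

#' @rdname read_depth_tsv
#' @param track a `depth_track`.
#' @param grid the `bin_grid` the track is on.
#' @export
write_depth_tsv <- function(track, grid, path) {
  df <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                   depth = format(track$depth, trim = TRUE,
                                  scientific = FALSE))
  write_bed(df, path, header = sprintf("individual: %s%s", track$id,
            if (track$corrected) " (GC-corrected)" else ""))
}

#' Read / write a numeric matrix with row-region annotation (TSV)
#'
#' Layout: chrom, start, end, then one column per individual.
#'
#' @param path file path.
#' @return list(regions, cn) matching the `cn_matrix` layout.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  regions <- df[, c("chrom", "start", "end")]
  cn <- as.matrix(df[, -(1:3), drop = FALSE])
  structure(list(regions = regions, cn = cn), class = "cn_matrix")
}

#' @rdname read_matrix_tsv
#' @param mat a `cn_matrix`.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- cbind(mat$regions, as.data.frame(mat$cn, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read / write gene models as a documented TSV
#'
#' Columns: gene_id, chrom, start, end, exon_starts, exon_ends (comma
#' lists, 0-based half-open).
#'
#' @param path file path.
#' @return list(genes, exons) data frames.
#' @export
read_genes_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  genes <- df[, c("gene_id", "chrom", "start", "end")]
  exons <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    s <- as.numeric(strsplit(df$exon_starts[i], ",")[[1]])
    e <- as.numeric(strsplit(df$exon_ends[i], ",")[[1]])
    if (length(s) != length(e) || any(e <= s))
      io_error(path, i + 1L, "malformed exon list")
    data.frame(gene_id = df$gene_id[i], chrom = df$chrom[i],
               start = s, end = e, stringsAsFactors = FALSE)
  }))
  list(genes = genes, exons = exons)
}

#' @rdname read_genes_tsv
#' @param genes,exons data frames as produced by [simulate_genome()].
#' @export
write_genes_tsv <- function(genes, exons, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    paste(genes$gene_id[i], genes$chrom[i],
          format(genes$start[i], scientific = FALSE, trim = TRUE),
          format(genes$end[i], scientific = FALSE, trim = TRUE),
          paste(format(ex$start, scientific = FALSE, trim = TRUE),
                collapse = ","),
          paste(format(ex$end, scientific = FALSE, trim = TRUE),
                collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(c("# coordinates: 0-based half-open",
               "gene_id\tchrom\tstart\tend\texon_starts\texon_ends", rows),
             path)
  invisible(path)
}

#' Read a term-to-gene annotation mapping (TSV: term_id, gene_id)
#' @param path file path.
#' @return data frame with term_id, gene_id.
#' @export
read_mapping_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df)))
    io_error(path, 1L, "mapping file needs term_id and gene_id columns")
  df[, c("term_id", "gene_id")]
}
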