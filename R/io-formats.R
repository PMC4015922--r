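#' Read a binned count track from a BedGraph file
#'
#' Parses a 4-column BedGraph (chrom, start, end, count) whose every row spans
#' exactly one bin of `bin_size` bp, aligned to the bin grid. Bins absent from
#' the file are filled with 0, so bin ordinal `i` of the returned per-chromosome
#' vector always covers the 0-based half-open interval
#' `[i * bin_size, (i + 1) * bin_size)`.
#'
#' @param path Path to a BedGraph file (tab- or space-separated, no header;
#'   `track` definition lines are skipped).
#' @param bin_size Bin width in bp; every row must satisfy `end - start == bin_size`.
#' @return A `binned_track`: list with `counts` (named list of per-chromosome
#'   numeric vectors) and `bin_size`.
#' @export
read_binned_track <- function(path, bin_size = 1000) {
  lines <- readLines(path)
  keep <- !grepl("^(track|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_binned_track(list(), bin_size))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- lineno[which(nf < 4L)[1L]]
    stop(sprintf("malformed BedGraph row at line %d of '%s': fewer than 4 fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  count <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(count))
  if (length(bad)) {
    stop(sprintf("malformed BedGraph row at line %d of '%s': non-numeric field",
                 lineno[bad[1L]], path))
  }
  badw <- which(end - start != bin_size | start %% bin_size != 0)
  if (length(badw)) {
    stop(sprintf(
      "inconsistent bin at line %d of '%s': [%g, %g) is not a %d bp grid bin",
      lineno[badw[1L]], path, start[badw[1L]], end[badw[1L]], bin_size))
  }
  if (any(count < 0)) {
    stop(sprintf("negative count at line %d of '%s'",
                 lineno[which(count < 0)[1L]], path))
  }
  counts <- list()
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    idx <- start[sel] %/% bin_size + 1L      # 1-based bin ordinal
    v <- numeric(max(idx))
    v[idx] <- count[sel]
    counts[[chr]] <- v
  }
  new_binned_track(counts, bin_size)
}

new_binned_track <- function(counts, bin_size) {
  structure(list(counts = counts, bin_size = bin_size), class = "binned_track")
}

#' Write a binned track as BedGraph
#'
#' Every bin is written, including zero bins, so that
#' `read_binned_track(write_binned_track(x))` round-trips exactly.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binned_track <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  bs <- track$bin_size
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$counts)) {
    v <- track$counts[[chr]]
    if (!length(v)) next
    i <- seq_along(v) - 1L
    writeLines(paste(chr, i * bs, (i + 1L) * bs, format(v, trim = TRUE,
                                                        scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin size %d bp\n",
              length(x$counts), x$bin_size))
  for (chr in names(x$counts)) {
    cat(sprintf("  %s: %d bins, total %.0f\n", chr, length(x$counts[[chr]]),
                sum(x$counts[[chr]])))
  }
  invisible(x)
}

#' Read a gene annotation table
#'
#' Accepts either a 4+ column TSV with header (`gene_id`, `chromosome`, `tss`,
#' `strand`) or headerless BED6 (chrom, start, end, name, score, strand), in
#' which case the TSS is the start for `+` genes and the end for `-` genes.
#'
#' @param path Path to the annotation file.
#' @return data.frame with columns gene_id, chromosome, tss, strand.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    ann <- ann[, c("gene_id", "chromosome", "tss", "strand")]
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED annotation needs 6 columns (strand required)")
    ann <- data.frame(gene_id = as.character(bed[[4L]]),
                      chromosome = as.character(bed[[1L]]),
                      tss = ifelse(bed[[6L]] == "+", bed[[2L]], bed[[3L]]),
                      strand = as.character(bed[[6L]]),
                      stringsAsFactors = FALSE)
  }
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(ann$tss < 0)) stop("tss must be >= 0")
  invisible(ann)
}

#' Write a gene annotation table (TSV with header)
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(ann[, c("gene_id", "chromosome", "tss", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM collection (JASPAR or TRANSFAC dialect)
#'
#' Counts are converted to column-normalized frequencies after adding a
#' pseudocount to every cell, and to log2-odds scores against a background
#' base composition (uniform by default).
#'
#' JASPAR: records start with `>motif_id tf_name`, followed by four base rows
#' (`A [ 4 19 0 ]` or plain numbers in A, C, G, T order). TRANSFAC: records
#' delimited by `AC` (accession) and `//`, with the matrix in numbered rows
#' (`01`..`NN`, four counts each) after a `P0`/`PO` header; the TF name is
#' taken from the `NA` line.
#'
#' @param path Path to the matrix file.
#' @param format `"jaspar"` or `"transfac"`.
#' @param pseudocount Added to every count cell before normalization.
#' @param background Length-4 base frequencies (A, C, G, T) for the log-odds.
#' @return A `pwm_collection`: list with `motifs` (named list of `pwm_motif`),
#'   `tf_map` (tf_name -> motif ids), `source_format`.
#' @export
read_pwm_collection <- function(path, format = c("jaspar", "transfac"),
                                pseudocount = 0.01,
                                background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path)
  motifs <- if (format == "jaspar") parse_jaspar(lines) else parse_transfac(lines)
  if (!length(motifs)) stop("no motifs parsed from '", path, "'")
  ids <- vapply(motifs, `[[`, "", "motif_id")
  if (anyDuplicated(ids)) stop("duplicate motif ids in '", path, "'")
  names(motifs) <- ids
  motifs <- lapply(motifs, function(m) {
    finalize_motif(m, pseudocount = pseudocount, background = background)
  })
  new_pwm_collection(motifs, format)
}

new_pwm_collection <- function(motifs, source_format = "synthetic") {
  tfs <- vapply(motifs, `[[`, "", "tf_name")
  tf_map <- split(names(motifs), tfs)
  structure(list(motifs = motifs, tf_map = tf_map,
                 source_format = source_format),
            class = "pwm_collection")
}

#' @export
print.pwm_collection <- function(x, ...) {
  cat(sprintf("pwm_collection: %d motif(s), %d TF(s) [%s]\n",
              length(x$motifs), length(x$tf_map), x$source_format))
  invisible(x)
}

# Counts -> pseudocounted frequencies and log2-odds vs background.
finalize_motif <- function(m, pseudocount, background) {
  counts <- m$counts
  if (any(counts < 0)) stop("negative count in motif ", m$motif_id)
  if (any(colSums(counts) == 0)) {
    stop("all-zero matrix column in motif ", m$motif_id)
  }
  cm <- counts + pseudocount
  freq <- sweep(cm, 2L, colSums(cm), "/")
  rownames(freq) <- c("A", "C", "G", "T")
  logodds <- log2(freq / background)
  rownames(logodds) <- rownames(freq)
  structure(list(motif_id = m$motif_id, tf_name = m$tf_name,
                 width = ncol(counts), counts = counts, freq = freq,
                 logodds = logodds),
            class = "pwm_motif")
}

parse_jaspar <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers found; not a JASPAR matrix file")
  ends <- c(hdr[-1L] - 1L, length(lines))
  lapply(seq_along(hdr), function(k) {
    head_fields <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "[ \t]+")[[1L]]
    motif_id <- head_fields[1L]
    tf_name <- if (length(head_fields) > 1L) {
      paste(head_fields[-1L], collapse = " ")
    } else motif_id
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    if (length(body) < 4L) stop("JASPAR record '", motif_id, "' lacks 4 base rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?|\\]", "", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("ragged JASPAR matrix for '", motif_id, "'")
    list(motif_id = motif_id, tf_name = tf_name,
         counts = do.call(rbind, rows))
  })
}

parse_transfac <- function(lines) {
  recs <- list()
  cur <- NULL
  for (l in lines) {
    tag <- substr(l, 1L, 2L)
    rest <- trimws(substr(l, 3L, nchar(l)))
    if (tag == "AC") {
      cur <- list(motif_id = rest, tf_name = NA_character_, rows = list())
    } else if (is.null(cur)) {
      next
    } else if (tag == "NA") {
      cur$tf_name <- rest
    } else if (grepl("^[0-9][0-9]$", tag)) {
      vals <- strsplit(rest, "[ \t]+")[[1L]]
      cur$rows[[length(cur$rows) + 1L]] <- as.numeric(vals[1:4])
    } else if (tag == "//") {
      if (length(cur$rows)) {
        if (is.na(cur$tf_name)) cur$tf_name <- cur$motif_id
        recs[[length(recs) + 1L]] <- list(
          motif_id = cur$motif_id, tf_name = cur$tf_name,
          counts = t(do.call(rbind, cur$rows)))  # rows are positions -> 4 x w
      }
      cur <- NULL
    }
  }
  recs
}

#' Write a PWM collection in JASPAR format
#' @param pwms A `pwm_collection`.
#' @param path Output path.
#' @export
write_pwm_collection <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in pwms$motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$tf_name), con)
    for (b in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write a results table as deterministic TSV
#'
#' Rows are sorted by the first column (the primary key), floats rendered at 6
#' significant digits, NA/NaN rendered as `"NA"`, so identical record sets
#' always produce byte-identical files.
#'
#' @param records data.frame (may have zero rows; header still written).
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  if (nrow(df) > 1L) df <- df[order(df[[1L]]), , drop = FALSE]
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      out <- ifelse(is.finite(v), format(signif(v, 6L), trim = TRUE,
                                         scientific = FALSE, digits = 15L),
                    ifelse(is.na(v), "NA", format(v)))
      df[[j]] <- out
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read promoter sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write promoter sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
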