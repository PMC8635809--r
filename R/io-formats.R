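#' Genomic interval tibbles
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end`, `name`
#' and `strand`. Coordinates are 0-based, half-open (`start` inclusive, `end`
#' exclusive), i.e. the native BED convention; every function in the package
#' uses this convention so there is a single coordinate system throughout.
#'
#' @param chrom character chromosome/contig names.
#' @param start,end integer 0-based half-open coordinates; `end > start`.
#' @param name optional feature names (recycled `""` if missing).
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
#' @examples
#' genomic_intervals("chr1", 10, 20)
genomic_intervals <- function(chrom, start, end, name = "", strand = ".") {
  tbl <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    strand = as.character(strand)
  )
  validate_intervals(tbl)
}

validate_intervals <- function(tbl, where = "intervals") {
  if (any(is.na(tbl$start)) || any(is.na(tbl$end))) {
    abort(sprintf("%s: non-integer coordinates.", where))
  }
  if (any(tbl$start < 0)) abort(sprintf("%s: start must be >= 0.", where))
  bad <- which(tbl$end <= tbl$start)
  if (length(bad)) {
    abort(sprintf("%s: end <= start at row %d.", where, bad[1]))
  }
  if (any(!nzchar(tbl$chrom)) || any(is.na(tbl$chrom))) {
    abort(sprintf("%s: empty chrom.", where))
  }
  ok <- tbl$strand %in% c("+", "-", ".")
  if (!all(ok)) abort(sprintf("%s: strand must be one of +, -, .", where))
  tbl
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Columns 4
#' (name) and 6 (strand) are honored when present; column 5 (score) is
#' ignored. Lines starting with `#`, `track` or `browser` are skipped.
#' Malformed lines (fewer than 3 fields, non-integer coordinates,
#' `end <= start`) raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @return Interval tibble (see [genomic_intervals()]); input order preserved.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines))
  if (!length(keep)) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    bad <- keep[which(n_fields < 3L)[1]]
    abort(sprintf("BED parse error at line %d: fewer than 3 fields.", bad))
  }
  get_col <- function(i) map_chr(fields, function(f) if (length(f) >= i) f[i] else NA_character_)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: non-integer coordinates.", keep[bad[1]]))
  }
  bad <- which(end <= start)
  if (length(bad)) {
    abort(sprintf("BED parse error at line %d: end <= start.", keep[bad[1]]))
  }
  name <- get_col(4)
  name[is.na(name)] <- ""
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  genomic_intervals(get_col(1), start, end, name, strand)
}

#' Write intervals as BED
#'
#' @param intervals interval tibble (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- validate_intervals(as_tibble(intervals))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   intervals$chrom, intervals$start, intervals$end,
                   ifelse(nzchar(intervals$name), intervals$name, "."),
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are deduplicated (first occurrence kept); duplicate
#' set names are an error, as are lines with fewer than 3 fields.
#'
#' @param path path to a GMT file.
#' @return Named list of unique gene-id character vectors, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT parse error at line %d: fewer than 3 fields.", short[1]))
  }
  nms <- map_chr(fields, 1)
  if (anyDuplicated(nms)) {
    abort(sprintf("GMT parse error: duplicate set name '%s'.", nms[duplicated(nms)][1]))
  }
  sets <- map(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  if (any(lengths(sets) == 0L) || any(unlist(sets) == "")) {
    abort("GMT parse error: empty set or empty gene id.")
  }
  attr(sets, "descriptions") <- setNames(map_chr(fields, 2), nms)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-id character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to the `descriptions` attribute of `sets`, else `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- map_chr(names(sets), function(nm) {
    paste(c(nm, unname(descriptions[nm]), unique(sets[[nm]])), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Position weight matrix objects
#'
#' A PWM stores a 4 x L count (or frequency) matrix over the alphabet
#' A, C, G, T together with the pseudocount and background composition used
#' for log-odds scoring (see [pwm_scan()]).
#'
#' @param name motif name.
#' @param counts 4 x L non-negative matrix; rows in A, C, G, T order (row
#'   names, if present, are used to reorder).
#' @param pseudocount positive pseudocount added per cell when scoring.
#' @param background length-4 probability vector (A, C, G, T); must sum to 1.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(name, counts, pseudocount = 0.25,
                    background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L) {
    abort("`counts` must be a 4 x L matrix (L >= 1).")
  }
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), c("A", "C", "G", "T"))) {
      abort("`counts` row names must be A, C, G, T.")
    }
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    rownames(counts) <- c("A", "C", "G", "T")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be finite and non-negative.")
  }
  check_number(pseudocount, "pseudocount", lower = .Machine$double.eps)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 positive probabilities summing to 1.")
  }
  structure(
    list(name = as.character(name), counts = counts,
         pseudocount = pseudocount,
         background = setNames(as.numeric(background), c("A", "C", "G", "T"))),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (length %d, pseudocount %g)\n",
              x$name, ncol(x$counts), x$pseudocount))
  print(round(x$counts, 2))
  invisible(x)
}

#' Read JASPAR-style PWM text
#'
#' Records consist of a `>name` header followed by four base rows of equal
#' length. Both the bracketed JASPAR layout (`A [ 1 2 3 ]`) and plain
#' whitespace-separated numeric rows are accepted. Rows labelled with a base
#' letter are mapped to that base; unlabelled rows are taken in A, C, G, T
#' order. Counts are stored in A, C, G, T row order regardless of file order.
#'
#' @param path path to the motif file.
#' @param pseudocount,background scoring parameters stored on each PWM
#'   (see [new_pwm()]).
#' @return List of `pwm` objects.
#' @export
read_jaspar_pwm <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("JASPAR parse error: no '>' header found.")
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      abort(sprintf("JASPAR parse error in record '%s': expected 4 base rows, got %d.",
                    name, length(body)))
    }
    labels <- toupper(sub("^([ACGTacgt])\\b.*", "\\1", body))
    labelled <- labels %in% c("A", "C", "G", "T")
    if (all(labelled)) {
      if (anyDuplicated(labels)) {
        abort(sprintf("JASPAR parse error in record '%s': duplicate base row.", name))
      }
      body <- body[match(c("A", "C", "G", "T"), labels)]
    } else if (any(labelled)) {
      abort(sprintf("JASPAR parse error in record '%s': mixed labelled/unlabelled rows.", name))
    }
    rows <- map(body, function(l) {
      l <- gsub("^[ACGTacgt]?\\s*\\[?", "", l)
      l <- gsub("\\]\\s*$", "", l)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(vals))) {
        abort(sprintf("JASPAR parse error in record '%s': non-numeric count.", name))
      }
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      abort(sprintf("JASPAR parse error in record '%s': rows of unequal length.", name))
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) {
      abort(sprintf("JASPAR parse error in record '%s': negative counts.", name))
    }
    out[[i]] <- new_pwm(name, counts, pseudocount, background)
  }
  out
}

#' Write PWMs in JASPAR text layout
#'
#' @param pwms list of `pwm` objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(map(pwms, function(p) {
    c(paste0(">", p$name),
      map_chr(c("A", "C", "G", "T"), function(b) {
        sprintf("%s  [ %s ]", b, paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' A TSV with at least `sample` and `condition` columns; `donor` and `time`
#' are carried through when present. Sample ids must be unique.
#'
#' @param path path to the TSV file.
#' @return Tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- as_tibble(utils::read.delim(path, check.names = FALSE,
                                       colClasses = "character"))
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  need <- c("sample", "condition")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    abort(sprintf("sample sheet is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample)) abort("sample sheet: duplicate sample ids.")
  sheet
}

#' Read a numeric matrix with a sample sheet
#'
#' Reads a TSV whose first column holds row ids (probes or genes) and whose
#' header holds sample ids. Columns are matched (and reordered) to the
#' sheet's `sample` column; a header sample absent from the sheet, or a
#' duplicated row id, is an error. For count matrices missing values are
#' rejected; for beta matrices they are allowed and flagged with a message.
#' An optional blocklist (e.g. SNP-overlapping probes) drops listed rows.
#'
#' @param path path to the TSV matrix.
#' @param sheet sample sheet tibble (see [read_sample_sheet()]).
#' @param kind `"beta"` or `"counts"`; controls missing-value policy and
#'   (for counts) an integer/non-negativity check.
#' @param blocklist optional character vector of row ids to drop, or a path
#'   to a one-id-per-line text file.
#' @return Numeric matrix with row ids as rownames and samples as colnames,
#'   columns in sheet order.
#' @export
read_matrix_tsv <- function(path, sheet, kind = c("beta", "counts"),
                            blocklist = NULL) {
  kind <- match.arg(kind)
  sheet <- validate_sample_sheet(sheet)
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate row id '%s' in %s.", ids[duplicated(ids)][1], path))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  extra <- setdiff(colnames(mat), sheet$sample)
  if (length(extra)) {
    abort(sprintf("matrix sample(s) absent from sheet: %s.", paste(extra, collapse = ", ")))
  }
  missing_cols <- setdiff(sheet$sample, colnames(mat))
  if (length(missing_cols)) {
    abort(sprintf("sheet sample(s) absent from matrix: %s.", paste(missing_cols, collapse = ", ")))
  }
  mat <- mat[, sheet$sample, drop = FALSE]
  storage.mode(mat) <- "numeric"
  if (kind == "counts") {
    if (anyNA(mat)) abort("count matrix contains missing values.")
    if (any(mat < 0) || any(mat != round(mat))) {
      abort("count matrix must contain non-negative integers.")
    }
  } else if (anyNA(mat)) {
    inform(sprintf("beta matrix: %d missing value(s) flagged.", sum(is.na(mat))))
  }
  if (!is.null(blocklist)) {
    if (length(blocklist) == 1L && file.exists(blocklist)) {
      blocklist <- readLines(blocklist)
    }
    blocklist <- blocklist[nzchar(blocklist)]
    mat <- mat[!rownames(mat) %in% blocklist, , drop = FALSE]
  }
  mat
}

#' Write a labelled numeric matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]; first column is named `id`.
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings returning plain named uppercase character
#' vectors, the sequence representation used by [pwm_scan()] and
#' [motif_enrichment()].
#'
#' @param path FASTA path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
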