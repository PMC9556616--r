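# Readers and writers for the BED family, GTF-derived TSS records, GWAS
# summary tables, expression tables, PWM files and k-mer weight tables.
#
# Everything downstream of this file sees 0-based half-open coordinates
# only; 1-based inputs (GTF, GWAS positions) are converted here.

.BED_DIALECTS <- list(
  bed3       = list(ncol = 3L, signal_col = NA_integer_),
  bed6       = list(ncol = 6L, signal_col = NA_integer_),
  broadpeak  = list(ncol = 9L, signal_col = 7L),
  narrowpeak = list(ncol = 10L, signal_col = 7L),
  bedgraph   = list(ncol = 4L, signal_col = 4L)
)

#' Read genomic intervals from a BED-family file
#'
#' Supports BED3, BED6, ENCODE broadPeak (9 columns), narrowPeak
#' (10 columns) and bedGraph.  Coordinates are taken as 0-based
#' half-open per the BED standard.  For broadPeak/narrowPeak the
#' signalValue column (7) populates \code{signal}; for bedGraph the
#' fourth column does.  \code{track}, \code{browser} and \code{#}
#' comment lines are skipped.
#'
#' @param path path to the file.
#' @param dialect one of \code{"bed3"}, \code{"bed6"},
#'   \code{"broadpeak"}, \code{"narrowpeak"}, \code{"bedgraph"}.
#' @return data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{signal}, rows in file order.
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed6", "broadpeak",
                                             "narrowpeak", "bedgraph")) {
  dialect <- match.arg(dialect)
  spec <- .BED_DIALECTS[[dialect]]
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      signal = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < spec$ncol)) {
    i <- which(nf < spec$ncol)[1]
    stop(sprintf("parse error at line %d: expected >= %d columns for %s, got %d",
                 lineno[i], spec$ncol, dialect, nf[i]))
  }
  get_col <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    stop(sprintf("parse error at line %d: non-integer coordinates or start >= end",
                 lineno[bad[1]]))
  }
  name <- if (dialect %in% c("bed6", "broadpeak", "narrowpeak")) {
    get_col(4)
  } else {
    rep(NA_character_, length(start))
  }
  signal <- if (!is.na(spec$signal_col)) {
    sg <- suppressWarnings(as.numeric(get_col(spec$signal_col)))
    if (anyNA(sg)) {
      stop(sprintf("parse error at line %d: non-numeric signal value",
                   lineno[which(is.na(sg))[1]]))
    }
    sg
  } else {
    rep(NA_real_, length(start))
  }
  data.frame(chrom = get_col(1), start = start, end = end,
             name = name, signal = signal, stringsAsFactors = FALSE)
}

#' Write genomic intervals to a BED-family file
#'
#' Inverse of \code{\link{read_intervals}}: output is tab-separated in
#' input row order with fixed float precision so that read/write
#' round-trips are stable.
#'
#' @param intervals data frame with \code{chrom}, \code{start},
#'   \code{end} and optionally \code{name}, \code{signal}.
#' @param path output path.
#' @param dialect output dialect (see \code{\link{read_intervals}}).
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(intervals, path,
                            dialect = c("bed3", "bed6", "broadpeak",
                                        "narrowpeak", "bedgraph")) {
  dialect <- match.arg(dialect)
  .check_intervals(intervals)
  n <- nrow(intervals)
  nm <- if ("name" %in% names(intervals)) intervals$name else rep(NA_character_, n)
  nm <- ifelse(is.na(nm), ".", nm)
  sg <- if ("signal" %in% names(intervals)) intervals$signal else rep(NA_real_, n)
  sg <- ifelse(is.na(sg), 0, sg)
  sgc <- sprintf("%.6g", sg)
  lines <- switch(dialect,
    bed3 = sprintf("%s\t%d\t%d", intervals$chrom, intervals$start, intervals$end),
    bed6 = sprintf("%s\t%d\t%d\t%s\t0\t.", intervals$chrom, intervals$start,
                   intervals$end, nm),
    broadpeak = sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1", intervals$chrom,
                        intervals$start, intervals$end, nm, sgc),
    narrowpeak = sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t-1", intervals$chrom,
                         intervals$start, intervals$end, nm, sgc),
    bedgraph = sprintf("%s\t%d\t%d\t%s", intervals$chrom, intervals$start,
                       intervals$end, sgc)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract transcription start sites from a GTF file
#'
#' One record per transcript (or gene, via \code{feature}) of an
#' included biotype, with a strand-aware 0-based TSS: the annotated
#' feature start for + strand and feature end minus one for - strand.
#' Duplicate (gene, position) pairs are deduplicated.
#'
#' @param gtf_path path to a GTF with gencode-style attributes
#'   (\code{gene_id}, \code{gene_name}, \code{gene_type} or
#'   \code{gene_biotype}).
#' @param types biotypes to keep.
#' @param feature which rows define a TSS, \code{"transcript"}
#'   (default) or \code{"gene"}.
#' @return data frame with \code{gene_id}, \code{gene_name},
#'   \code{gene_type}, \code{chrom}, \code{tss_position} (0-based),
#'   \code{strand}.
#' @export
read_tss <- function(gtf_path, types = c("protein_coding", "lncRNA"),
                     feature = c("transcript", "gene")) {
  feature <- match.arg(feature)
  if (!file.exists(gtf_path)) stop("file not found: ", gtf_path)
  lines <- readLines(gtf_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) stop("parse error: GTF line with fewer than 9 columns")
  feat <- vapply(fields, `[[`, character(1), 3)
  keep <- feat == feature
  if (!any(keep)) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      gene_type = character(), chrom = character(),
                      tss_position = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- fields[keep]
  attr_str <- vapply(fields, `[[`, character(1), 9)
  get_attr <- function(key) {
    m <- regmatches(attr_str,
                    regexpr(paste0(key, ' "[^"]*"'), attr_str))
    out <- rep(NA_character_, length(attr_str))
    hit <- grepl(paste0(key, ' "'), attr_str)
    out[hit] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                    regmatches(attr_str, regexpr(paste0(key, ' "[^"]*"'),
                                                 attr_str)))
    out
  }
  gene_id <- get_attr("gene_id")
  gtype <- get_attr("gene_type")
  if (all(is.na(gtype))) gtype <- get_attr("gene_biotype")
  if (anyNA(gene_id) || anyNA(gtype)) {
    stop("parse error: missing gene_id or gene_type/gene_biotype attribute")
  }
  gene_name <- get_attr("gene_name")
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  chrom <- vapply(fields, `[[`, character(1), 1)
  start1 <- as.integer(vapply(fields, `[[`, character(1), 4))  # 1-based
  end1 <- as.integer(vapply(fields, `[[`, character(1), 5))
  strand <- vapply(fields, `[[`, character(1), 7)
  sel <- gtype %in% types
  # strand rule: + TSS = 0-based start; - TSS = 0-based end - 1
  tss <- ifelse(strand == "-", end1 - 1L, start1 - 1L)
  out <- data.frame(gene_id = gene_id[sel], gene_name = gene_name[sel],
                    gene_type = gtype[sel], chrom = chrom[sel],
                    tss_position = tss[sel], strand = strand[sel],
                    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("gene_id", "tss_position")]), , drop = FALSE]
}

#' Read a GWAS summary-statistics table
#'
#' Positions are converted from 1-based to the package's internal
#' 0-based convention.  Rows with non-numeric p-value or effect size
#' are dropped; the drop count is attached as attribute
#' \code{"n_dropped"} and reported with a message.
#'
#' @param path delimited text file with a header row.
#' @param column_map named list mapping the fields \code{variant},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{beta},
#'   \code{p} to column names in the header.
#' @param sep field separator.
#' @return data frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos} (0-based), \code{ref_allele}, \code{alt_allele},
#'   \code{beta}, \code{pvalue}.
#' @export
read_gwas_summary <- function(path,
                              column_map = list(variant = "variant",
                                                chrom = "chrom", pos = "pos",
                                                ref = "ref", alt = "alt",
                                                beta = "beta", p = "p"),
                              sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE)
  needed <- c("variant", "chrom", "pos", "ref", "alt", "beta", "p")
  if (!all(needed %in% names(column_map))) {
    stop("column_map must name: ", paste(needed, collapse = ", "))
  }
  cols <- unlist(column_map[needed])
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0) {
    stop("column(s) not in header: ", paste(missing_cols, collapse = ", "))
  }
  pval <- suppressWarnings(as.numeric(tab[[column_map$p]]))
  beta <- suppressWarnings(as.numeric(tab[[column_map$beta]]))
  pos1 <- suppressWarnings(as.integer(tab[[column_map$pos]]))
  keep <- !is.na(pval) & !is.na(beta) & !is.na(pos1) & pval > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_gwas_summary: dropped %d row(s) with non-numeric p/beta/pos",
                    n_dropped))
  }
  out <- data.frame(
    variant_id = tab[[column_map$variant]][keep],
    chrom = tab[[column_map$chrom]][keep],
    pos = pos1[keep] - 1L,  # to 0-based
    ref_allele = tab[[column_map$ref]][keep],
    alt_allele = tab[[column_map$alt]][keep],
    beta = beta[keep],
    pvalue = pval[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read an expression table (genes x samples, FPKM)
#'
#' @param path TSV whose first column is the gene id and remaining
#'   columns are samples.
#' @param sample_map optional data frame with columns \code{sample} and
#'   \code{cell_type}; attached as attribute \code{"sample_map"}.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_table <- function(path, sample_map = NULL) {
  tab <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  if (!is.null(sample_map)) {
    stopifnot(all(colnames(mat) %in% sample_map$sample))
    attr(mat, "sample_map") <- sample_map
  }
  mat
}

#' Read position weight matrices
#'
#' Accepts either a MEME-like file of probability blocks
#' (\code{MOTIF <name>} followed by one line of four probabilities per
#' motif position) or a 4-column TSV with a \code{tf} grouping column.
#'
#' @param path PWM file.
#' @return named list of matrices (positions x 4, columns A,C,G,T),
#'   row-normalized probabilities.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (any(grepl("^MOTIF\\b", lines))) {
    idx <- grep("^MOTIF\\b", lines)
    names_ <- sub("^MOTIF\\s+", "", lines[idx])
    bounds <- c(idx, length(lines) + 1L)
    out <- list()
    for (i in seq_along(idx)) {
      block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
      block <- block[grepl("^[0-9.eE+ \t-]+$", block)]
      mat <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
      if (is.null(mat) || ncol(mat) != 4) {
        stop("parse error: PWM block for ", names_[i],
             " does not have 4 columns")
      }
      colnames(mat) <- DNA_BASES
      out[[names_[i]]] <- mat / rowSums(mat)
    }
    out
  } else {
    tab <- read.delim(path, sep = "\t", header = TRUE)
    stopifnot(all(c("tf", "A", "C", "G", "T") %in% names(tab)))
    lapply(split(tab, tab$tf), function(d) {
      mat <- as.matrix(d[, DNA_BASES])
      rownames(mat) <- NULL
      mat / rowSums(mat)
    })
  }
}

#' Write PWMs in the MEME-like block format read by [read_pwms()]
#' @param pwms named list of positions x 4 probability matrices.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    writeLines(paste("MOTIF", nm), con)
    mat <- pwms[[nm]]
    writeLines(apply(mat, 1, function(r) paste(sprintf("%.6f", r),
                                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read a k-mer weight table
#'
#' @param path TSV with columns \code{kmer} and \code{weight}
#'   (optionally \code{tf} for multi-TF files).
#' @return if a \code{tf} column is present, a named list of
#'   named-numeric weight vectors; otherwise a single named vector.
#' @export
read_kmer_weights <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE)
  stopifnot(all(c("kmer", "weight") %in% names(tab)))
  mk <- function(d) setNames(as.numeric(d$weight), toupper(d$kmer))
  if ("tf" %in% names(tab)) lapply(split(tab, tab$tf), mk) else mk(tab)
}
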