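#' Read cfDNA fragment intervals from a BEDPE/BED file
#'
#' Fragments are expected as one interval per line: the first three columns
#' are chromosome, 0-based start and 0-based exclusive end (properly paired
#' mates already collapsed to a single fragment interval). Extra columns are
#' ignored, so plain 6-column BED also parses. Files may be gzip-compressed.
#'
#' @param path Path to a tab-separated BEDPE/BED file.
#' @param min_len,max_len Fragment length bounds in bp; fragments with
#'   length outside `[min_len, max_len)` are dropped. The default ingest
#'   window `[65, 1000)` is deliberately loose; individual analyses apply
#'   their own tighter windows (e.g. FSD uses 65-400 bp).
#' @return A `data.table` with columns `chrom`, `start`, `end`, `length`,
#'   carrying an attribute `n_dropped` with the number of length-filtered
#'   records.
#' @export
read_fragments <- function(path, min_len = 65L, max_len = 1000L) {
  stopifnot(min_len <= max_len)
  if (file.exists(path) && !grepl("\\.gz$", path) && file.size(path) == 0) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), length = integer())
    data.table::setattr(out, "n_dropped", 0L)
    return(out)
  }
  dt <- tryCatch(
    fread_auto(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse BEDPE file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), length = integer())
    data.table::setattr(out, "n_dropped", 0L)
    return(out)
  }
  if (ncol(dt) < 3L) stop("BEDPE file needs at least 3 columns", call. = FALSE)
  out <- dt[, 1:3]
  data.table::setnames(out, c("chrom", "start", "end"))
  bad <- which(!is.finite(out$start) | !is.finite(out$end))
  if (length(bad)) {
    stop("malformed BEDPE line ", bad[1], " in '", path, "'", call. = FALSE)
  }
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  nonpos <- which(out$end <= out$start)
  if (length(nonpos)) {
    stop("end <= start at line ", nonpos[1], " in '", path, "'", call. = FALSE)
  }
  out[, length := end - start]
  keep <- out$length >= min_len & out$length < max_len
  dropped <- sum(!keep)
  out <- out[keep]
  data.table::setattr(out, "n_dropped", dropped)
  out[]
}

#' Write fragment intervals as 3-column BEDPE
#'
#' @param fragments A fragment table as returned by [read_fragments()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

#' Load a reference genome from FASTA
#'
#' Sequences are uppercased; a reverse-complemented copy of each chromosome
#' is precomputed so that minus-strand motif extraction reduces to plain
#' substring lookups.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return An object of class `ref_genome` with elements `seq` (named
#'   character vector), `rc` (reverse complements) and `lengths`.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  names(rc) <- nm
  structure(list(seq = seqs, rc = rc, lengths = nchar(seqs)),
            class = "ref_genome")
}

#' Extract genome sequence on 0-based half-open coordinates
#'
#' @param genome A `ref_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval `[start, end)`.
#' @return The `end - start` character sequence.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "ref_genome"))
  if (!chrom %in% names(genome$seq)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  L <- genome$lengths[[chrom]]
  if (any(start < 0) || any(end > L) || any(end <= start)) {
    stop("out-of-range lookup on ", chrom, call. = FALSE)
  }
  substring(genome$seq[[chrom]], start + 1L, end)
}

#' Read gene annotations from a BED-like file
#'
#' Required columns (tab-separated, no header): chrom, body start, body end
#' (0-based half-open), gene_id, strand. Optional columns 6 and 7 carry an
#' annotation-supplied promoter interval. The TSS is derived from strand:
#' `body_start` on `+`, `body_end - 1` on `-`.
#'
#' @param path Path to the annotation file.
#' @param promoter_rule Either `"tss1500"` (promoter = TSS +/- 1500 bp,
#'   the profile-figure convention) or `"annotation"` (use the interval
#'   supplied in columns 6-7, Ensembl-regulatory-build style).
#' @param promoter_flank Half-width in bp for the `"tss1500"` rule.
#' @return A `data.table` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `body_start`, `body_end`, `promoter_start`, `promoter_end`.
#' @export
read_annotations <- function(path, promoter_rule = c("tss1500", "annotation"),
                             promoter_flank = 1500L) {
  promoter_rule <- match.arg(promoter_rule)
  dt <- fread_auto(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 5L) {
    stop("annotation file needs columns chrom,start,end,gene_id,strand",
         call. = FALSE)
  }
  ann <- dt[, 1:5]
  data.table::setnames(ann, c("chrom", "body_start", "body_end",
                              "gene_id", "strand"))
  if (anyDuplicated(ann$gene_id)) {
    stop("duplicate gene_id: ", ann$gene_id[duplicated(ann$gene_id)][1],
         call. = FALSE)
  }
  badstrand <- setdiff(unique(ann$strand), c("+", "-"))
  if (length(badstrand)) {
    stop("unknown strand symbol: '", badstrand[1], "'", call. = FALSE)
  }
  if (any(ann$body_end <= ann$body_start)) {
    stop("gene with body_end <= body_start", call. = FALSE)
  }
  ann[, tss := ifelse(strand == "+", body_start, body_end - 1L)]
  if (promoter_rule == "annotation") {
    if (ncol(dt) < 7L) {
      stop("promoter_rule='annotation' needs promoter columns 6 and 7",
           call. = FALSE)
    }
    ann[, promoter_start := as.integer(dt[[6]])]
    ann[, promoter_end := as.integer(dt[[7]])]
  } else {
    ann[, promoter_start := as.integer(tss - promoter_flank)]
    ann[, promoter_end := as.integer(tss + promoter_flank)]
  }
  data.table::setcolorder(ann, c("gene_id", "chrom", "strand", "tss",
                                 "body_start", "body_end",
                                 "promoter_start", "promoter_end"))
  ann[]
}

#' Read per-CpG methylation calls
#'
#' Expects tab-separated rows chrom, 0-based position, methylated count,
#' total count (bedGraph-derived count format). Rows must be unique per
#' (chrom, pos).
#'
#' @param path Path to the calls file.
#' @return A `data.table` with columns `chrom`, `pos`, `methylated_count`,
#'   `total_count`, `ratio`.
#' @export
read_methylation <- function(path) {
  dt <- fread_auto(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) {
    stop("methylation file needs columns chrom,pos,methylated,total",
         call. = FALSE)
  }
  dt <- dt[, 1:4]
  data.table::setnames(dt, c("chrom", "pos", "methylated_count",
                             "total_count"))
  if (any(dt$total_count < 1L)) {
    stop("CpG with total_count < 1", call. = FALSE)
  }
  if (any(dt$methylated_count > dt$total_count)) {
    stop("methylated_count exceeds total_count", call. = FALSE)
  }
  if (any(dt$methylated_count < 0L)) {
    stop("negative methylated_count", call. = FALSE)
  }
  if (anyDuplicated(dt[, c("chrom", "pos")])) {
    stop("duplicate CpG position", call. = FALSE)
  }
  dt[, ratio := methylated_count / total_count]
  dt[]
}

#' Write / read a sample-by-feature matrix as TSV
#'
#' First column holds sample identifiers; remaining columns one feature
#' each. Missing values round-trip as the literal `NA`.
#'
#' @param m Numeric matrix with sample rownames and feature colnames.
#' @param path Output (input) path, `.gz` transparent.
#' @return `read_feature_table` returns the matrix; `write_feature_table`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (anyDuplicated(colnames(m))) stop("duplicate feature name", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate sample id", call. = FALSE)
  # serialise doubles at full precision so read(write(M)) is bit-identical
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  chr[is.na(m)] <- NA_character_
  dt <- data.table::data.table(sample_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(chr))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE,
                     compress = "auto")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- fread_auto(path, header = TRUE, sep = "\t", na.strings = "NA",
                          colClasses = list(character = 1))
  if (anyDuplicated(names(dt)[-1])) {
    stop("duplicate feature name", call. = FALSE)
  }
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read the sample metadata table
#'
#' Tab-separated with header; required columns `sample_id`, `cohort`
#' (train/validation), `label` (cancer/benign/healthy); optional `stage`
#' and `subtype`.
#'
#' @param path Path to the metadata TSV.
#' @return A `data.table`, one row per sample.
#' @export
read_sample_meta <- function(path) {
  dt <- fread_auto(path, header = TRUE, sep = "\t",
                          colClasses = list(character = "sample_id"))
  req <- c("sample_id", "cohort", "label")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(dt$sample_id)) stop("duplicate sample_id", call. = FALSE)
  badlab <- setdiff(unique(dt$label), c("cancer", "benign", "healthy"))
  if (length(badlab)) {
    stop("unknown label: ", badlab[1], call. = FALSE)
  }
  if (!"stage" %in% names(dt)) dt[, stage := NA_character_]
  if (!"subtype" %in% names(dt)) dt[, subtype := "none"]
  dt[]
}
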