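# Readers and writers for the standard formats consumed by the pipeline:
# MAF alignment blocks, BED-family interval files, ortholog family tables
# and species metadata. Everything is normalised to 0-based half-open
# coordinates on read (MAF and BED already use them natively).

#' Recognised phylogenetic groups
#'
#' The five vertebrate groups used to summarise conservation, plus the
#' special `Reference` group that tags the reference species.
#' @return character vector of group labels.
#' @export
phylo_groups <- function() {
  c("Boreoeutheria", "Atlantogenata", "MonotremesMarsupials",
    "SauropsidsAmphibians", "Teleosts")
}

# ---------------------------------------------------------------------------
# MAF

#' Read a MAF file into a list of alignment blocks
#'
#' Parses the UCSC MAF dialect: `a` lines open a block, `s` lines carry
#' aligned rows; `e`, `i`, `q` and comment lines are tolerated and ignored.
#' The species of a row is the part of the `src` field before the first
#' dot, the chromosome the part after it. Row starts are native 0-based
#' (for `-` strand rows, in the reverse-complemented frame, as in MAF;
#' see [maf_row_forward()]).
#'
#' @param path MAF file (plain or gzip).
#' @param reference species id of the reference row; defaults to the
#'   species of the first row of the first block. Every block must contain
#'   a row for the reference species.
#' @return list of `maf_block` objects: each a list with `ref` (reference
#'   species id) and `rows`, a data.frame with columns `species`, `chrom`,
#'   `start`, `length`, `strand`, `src_size`, `seq`.
#' @export
read_maf <- function(path, reference = NULL) {
  lines <- .read_lines(path)
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0L) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tag <- substr(ln, 1L, 1L)
    if (tag == "a") {
      flush()
      cur <- data.frame(species = character(), chrom = character(),
                        start = integer(), length = integer(),
                        strand = character(), src_size = integer(),
                        seq = character(), line = integer(),
                        stringsAsFactors = FALSE)
    } else if (tag == "s") {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 7L)
        stop("malformed MAF 's' line at line ", i, ": expected 7 fields")
      if (is.null(cur))
        stop("MAF 's' line outside a block at line ", i)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      cur[nrow(cur) + 1L, ] <- list(species, chrom, as.integer(f[3]),
                                    as.integer(f[4]), f[5],
                                    as.integer(f[6]), f[7], i)
    }
    # e / i / q lines fall through, ignored
  }
  flush()
  if (length(blocks) == 0L) return(list())
  if (is.null(reference)) reference <- blocks[[1]]$species[1]
  prev_ref_start <- -Inf
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    widths <- nchar(rows$seq)
    if (length(unique(widths)) != 1L)
      stop("malformed MAF block: unequal gapped row lengths at line ",
           rows$line[which(widths != widths[1])[1]])
    ungapped <- nchar(gsub("-", "", rows$seq, fixed = TRUE))
    bad <- which(ungapped != rows$length)
    if (length(bad))
      stop("malformed MAF block: ungapped length ", ungapped[bad[1]],
           " != declared length ", rows$length[bad[1]],
           " at line ", rows$line[bad[1]])
    if (!reference %in% rows$species)
      stop("MAF block starting near line ", rows$line[1],
           " has no row for reference species '", reference, "'")
    ri <- match(reference, rows$species)
    if (rows$start[ri] <= prev_ref_start)
      stop("reference coordinates not strictly increasing across blocks ",
           "at line ", rows$line[ri])
    prev_ref_start <- rows$start[ri]
    rows$line <- NULL
    out[[b]] <- structure(list(ref = reference, rows = rows),
                          class = "maf_block")
  }
  out
}

#' @export
print.maf_block <- function(x, ...) {
  ri <- match(x$ref, x$rows$species)
  cat(sprintf("maf_block: %d rows x %d columns, reference %s.%s:%d-%d\n",
              nrow(x$rows), nchar(x$rows$seq[1]), x$ref, x$rows$chrom[ri],
              x$rows$start[ri], x$rows$start[ri] + x$rows$length[ri]))
  invisible(x)
}

#' Write alignment blocks to a MAF file
#'
#' @param blocks list of `maf_block` objects (as from [read_maf()]).
#' @param path output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    r <- b$rows
    writeLines(sprintf("s %s.%s %d %d %s %d %s", r$species, r$chrom,
                       r$start, r$length, r$strand, r$src_size, r$seq), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Forward-strand coordinates of a MAF row
#'
#' MAF stores `-` strand row starts in the reverse-complemented frame;
#' this converts one row to forward-strand 0-based half-open coordinates.
#'
#' @param row one row of a block's `rows` data.frame (a list or
#'   single-row data.frame with `start`, `length`, `strand`, `src_size`).
#' @return numeric vector `c(start, end)` on the forward strand.
#' @export
maf_row_forward <- function(row) {
  if (row$strand == "-") {
    c(row$src_size - row$start - row$length, row$src_size - row$start)
  } else {
    c(row$start, row$start + row$length)
  }
}

# ---------------------------------------------------------------------------
# BED-family interval formats

#' Read genomic intervals (BED / bedGraph / broadPeak / BEDPE)
#'
#' All formats are 0-based half-open and pass through unchanged. Records
#' with `start >= end` are rejected with a warning; the number rejected is
#' recorded in the `n_rejected` attribute. Overlapping intervals are kept
#' as-is, never merged.
#'
#' @param path interval file (plain or gzip), whitespace-delimited.
#' @param format one of `"bed"`, `"bedgraph"`, `"broadpeak"`, `"bedpe"`.
#' @return For the single-interval formats, a data.frame with `chrom`,
#'   `start`, `end`, and where available `name`, `value`, `strand`
#'   (bedGraph: 4th column is the value, or the 5th when a name column is
#'   present; broadPeak: `value` is the 7th column, signalValue). For
#'   `"bedpe"`, a data.frame of interaction pairs: `chrom1`, `start1`,
#'   `end1`, `chrom2`, `start2`, `end2`, `gene_id` (taken from the BEDPE
#'   name column).
#' @export
read_intervals <- function(path,
                           format = c("bed", "bedgraph", "broadpeak",
                                      "bedpe")) {
  format <- match.arg(format)
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    out <- if (format == "bedpe") {
      data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                 chrom2 = character(), start2 = integer(), end2 = integer(),
                 gene_id = character(), stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  f <- strsplit(lines, "[ \t]+")
  nf <- lengths(f)
  get <- function(i) vapply(f, function(x) if (length(x) >= i) x[i]
                            else NA_character_, character(1))
  if (format == "bedpe") {
    if (any(nf < 7L)) stop("BEDPE requires >= 7 columns (name carries the gene id)")
    out <- data.frame(chrom1 = get(1), start1 = as.integer(get(2)),
                      end1 = as.integer(get(3)), chrom2 = get(4),
                      start2 = as.integer(get(5)), end2 = as.integer(get(6)),
                      gene_id = get(7), stringsAsFactors = FALSE)
    bad <- out$start1 >= out$end1 | out$start2 >= out$end2
    if (any(bad)) warning(sum(bad), " BEDPE record(s) with start >= end rejected")
    res <- out[!bad, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "n_rejected") <- sum(bad)
    return(res)
  }
  out <- data.frame(chrom = get(1), start = as.integer(get(2)),
                    end = as.integer(get(3)), stringsAsFactors = FALSE)
  if (format == "bed") {
    if (all(nf >= 4L)) out$name <- get(4)
    if (all(nf >= 5L)) out$value <- as.numeric(get(5))
    if (all(nf >= 6L)) out$strand <- get(6)
  } else if (format == "bedgraph") {
    # canonical bedGraph is chrom/start/end/value; a 5-column variant with
    # a name in column 4 and the value in column 5 is also accepted
    if (all(nf >= 5L)) {
      out$name <- get(4)
      out$value <- as.numeric(get(5))
    } else {
      out$value <- as.numeric(get(4))
    }
  } else if (format == "broadpeak") {
    if (any(nf < 7L)) stop("broadPeak requires >= 7 columns")
    out$name <- get(4)
    out$strand <- get(6)
    out$value <- as.numeric(get(7))
  }
  if (!is.null(out$value) && any(out$value < 0, na.rm = TRUE))
    stop("negative signal values are not allowed")
  bad <- out$start >= out$end
  if (any(bad)) warning(sum(bad), " interval(s) with start >= end rejected")
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- sum(bad)
  res
}

#' Write intervals in BED-family formats
#'
#' @param x data.frame as returned by [read_intervals()].
#' @param path output file.
#' @param format one of `"bed"`, `"bedgraph"`, `"bedpe"`.
#' @export
write_intervals <- function(x, path, format = c("bed", "bedgraph", "bedpe")) {
  format <- match.arg(format)
  lines <- if (format == "bedpe") {
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", x$chrom1, x$start1, x$end1,
            x$chrom2, x$start2, x$end2, x$gene_id)
  } else if (format == "bedgraph") {
    if (!is.null(x$name))
      sprintf("%s\t%d\t%d\t%s\t%s", x$chrom, x$start, x$end, x$name,
              format(x$value, trim = TRUE, scientific = FALSE))
    else
      sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end,
              format(x$value, trim = TRUE, scientific = FALSE))
  } else {
    base <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
    if (!is.null(x$name)) {
      sc <- if (!is.null(x$value)) format(x$value, trim = TRUE,
                                          scientific = FALSE) else "0"
      base <- paste(base, x$name, sc, sep = "\t")
      if (!is.null(x$strand)) base <- paste(base, x$strand, sep = "\t")
    }
    base
  }
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ortholog families and species metadata

#' Read an ortholog family table
#'
#' TSV with header `family_id, species_id, gene_id, chrom, start, end,
#' strand` (0-based half-open). One row per gene placement; a species may
#' carry several rows per family (paralogs) or none (absent /
#' mis-annotated). Exact duplicate rows are dropped with a warning.
#'
#' @param path TSV file (plain or gzip).
#' @param species_meta optional data.frame from [read_species_meta()]; if
#'   supplied, unknown `species_id`s raise an error listing the offenders.
#' @return data.frame keyed by (`family_id`, `species_id`, `gene_id`).
#' @export
read_ortholog_table <- function(path, species_meta = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "species_id", "gene_id", "chrom", "start", "end",
            "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("ortholog table missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(x$family_id, x$species_id, x$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (family, species, gene) row(s) dropped")
    x <- x[!duplicated(key), , drop = FALSE]
  }
  if (!is.null(species_meta)) {
    unknown <- setdiff(unique(x$species_id), species_meta$species_id)
    if (length(unknown))
      stop("unknown species_id in ortholog table: ",
           paste(unknown, collapse = ", "))
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_ortholog_table
#' @param x ortholog table data.frame.
#' @export
write_ortholog_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the species metadata table
#'
#' TSV with header `species_id, phylo_group, genome_size, C_e, excluded`
#' and optionally `R_e`. `C_e` is the sequencing-coverage corrective
#' factor in [0,1] (finished/high-coverage assemblies 1.0, ~2x drafts
#' 0.5); `R_e`, when absent, is filled later by
#' [compute_synteny_levels()]. Exactly one species must carry
#' `phylo_group == "Reference"`; `excluded` flags over-fragmented
#' assemblies that must be skipped by the linkage scoring.
#'
#' @param path TSV file (plain or gzip).
#' @return validated data.frame.
#' @export
read_species_meta <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_species_meta(x)
}

.validate_species_meta <- function(x) {
  need <- c("species_id", "phylo_group", "genome_size", "C_e", "excluded")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("species metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$species_id))
    stop("duplicate species_id in species metadata")
  ok_groups <- c(phylo_groups(), "Reference")
  bad <- setdiff(unique(x$phylo_group), ok_groups)
  if (length(bad))
    stop("unknown phylo_group: ", paste(bad, collapse = ", "))
  if (sum(x$phylo_group == "Reference") != 1L)
    stop("exactly one species must have phylo_group 'Reference'")
  if (any(x$genome_size <= 0)) stop("genome_size must be > 0")
  if (any(x$C_e < 0 | x$C_e > 1)) stop("C_e must lie in [0, 1]")
  x$excluded <- as.logical(x$excluded)
  if (anyNA(x$excluded)) stop("excluded must be TRUE/FALSE")
  if (!is.null(x$R_e) && any(!is.na(x$R_e) & (x$R_e < 0 | x$R_e > 1)))
    stop("R_e must lie in [0, 1]")
  rownames(x) <- NULL
  x
}

#' @rdname read_species_meta
#' @param x species metadata data.frame.
#' @export
write_species_meta <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
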