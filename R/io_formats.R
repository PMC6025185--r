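#' Read a domain-protein structural-neighbor table
#'
#' Tab-separated file with header columns `domain_id`, `protein_id`, `psd`
#' (protein structure distance, dimensionless, >= 0; lower = more similar).
#' Duplicate (domain, protein) rows are collapsed to the minimum PSD.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `domain_id`, `protein_id`, `psd`.
#' @export
read_neighbor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "protein_id", "psd")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("neighbor table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  df <- df[need]
  if (!is.numeric(df$psd)) stop("psd column is not numeric")
  if (any(is.na(df$psd))) stop("psd column contains missing values")
  if (any(df$psd < 0)) {
    stop(sprintf("negative psd at row %d", which(df$psd < 0)[1]))
  }
  # min-PSD dedup per (domain, protein)
  o <- order(df$domain_id, df$protein_id, df$psd)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[c("domain_id", "protein_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a neighbor table
#' @param df data.frame as returned by [read_neighbor_table()].
#' @param path Output path.
#' @export
write_neighbor_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular hits (outfmt 6, optional qcovs)
#'
#' Standard 12-column BLAST tabular order (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). A 13th column,
#' if present, is taken as `qcovs` (query coverage percent). With 12
#' columns, query coverage is computed as `(qend - qstart + 1) /
#' query_length` from a supplied query-length table. E-values printed as 0
#' are clamped to `evalue_floor` so `-log(E)` stays finite.
#'
#' @param path Path to the tabular file (no header, `#` comments allowed).
#' @param query_lengths Named numeric vector (names = query ids); required
#'   when the file has no qcovs column.
#' @param evalue_floor Positive clamp for zero E-values (default 1e-180).
#' @param drop_self Drop rows with `qseqid == sseqid`.
#' @return data.frame with columns `query_id`, `subject_id`, `pident`,
#'   `evalue`, `coverage` (fraction in \[0,1\]).
#' @export
read_blast_tab <- function(path, query_lengths = NULL,
                           evalue_floor = 1e-180, drop_self = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      pident = numeric(0), evalue = numeric(0),
                      coverage = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) > 1L || !(ncols %in% c(12L, 13L))) {
    stop("BLAST tabular file must have a uniform 12 or 13 columns")
  }
  getcol <- function(i) vapply(fields, `[`, "", i)
  ev <- suppressWarnings(as.numeric(getcol(11L)))
  if (any(is.na(ev))) {
    stop(sprintf("non-numeric evalue at line %d", which(is.na(ev))[1]))
  }
  ev[ev <= 0] <- evalue_floor
  qid <- getcol(1L); sid <- getcol(2L)
  if (ncols == 13L) {
    cov <- as.numeric(getcol(13L)) / 100
  } else {
    if (is.null(query_lengths)) {
      stop("12-column BLAST file needs a query_lengths table for coverage")
    }
    qs <- as.numeric(getcol(7L)); qe <- as.numeric(getcol(8L))
    ql <- query_lengths[qid]
    if (any(is.na(ql))) {
      stop(sprintf("no query length for '%s'", qid[which(is.na(ql))[1]]))
    }
    cov <- (qe - qs + 1) / as.numeric(ql)
  }
  df <- data.frame(query_id = qid, subject_id = sid,
                   pident = as.numeric(getcol(3L)),
                   evalue = ev, coverage = pmin(pmax(cov, 0), 1),
                   stringsAsFactors = FALSE)
  if (drop_self) df <- df[df$query_id != df$subject_id, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a PSI-BLAST ASCII PSSM profile
#'
#' Parses the `-Q`-style ASCII PSSM: header lines, then one row per
#' position carrying the position index, the residue, and (first block)
#' 20 integer log-odds scores. The second block (weighted percentages)
#' and the K/lambda footer are ignored.
#'
#' @param path Path to the PSSM file.
#' @param domain_id Identifier to attach (default: file basename without
#'   extension).
#' @return Object of class `pssm_profile`: list with `domain_id`,
#'   `sequence` (residue string), `matrix` (L x 20 numeric, columns named
#'   by the amino-acid header order).
#' @export
read_pssm_ascii <- function(path, domain_id = NULL) {
  if (is.null(domain_id)) {
    domain_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  # matrix rows: integer, residue letter, then >= 20 integers
  row_re <- "^\\s*\\d+\\s+[A-Za-z*]\\s+(-?\\d+\\s+){19}-?\\d+"
  is_row <- grepl(row_re, lines)
  if (!any(is_row)) stop(sprintf("no PSSM matrix rows found in %s", path))
  rows <- lines[is_row]
  toks <- strsplit(trimws(rows), "\\s+")
  pos <- as.integer(vapply(toks, `[`, "", 1L))
  res <- vapply(toks, `[`, "", 2L)
  nscores <- lengths(toks) - 2L
  if (any(nscores < 20L)) {
    stop(sprintf("PSSM row at position %d has %d score columns (need >= 20)",
                 pos[which(nscores < 20L)[1]], nscores[which(nscores < 20L)[1]]))
  }
  mat <- t(vapply(toks, function(tk) as.numeric(tk[3:22]), numeric(20)))
  if (any(is.na(mat))) stop("non-numeric PSSM score encountered")
  # column names from the amino-acid header line if present
  hdr <- lines[grepl("^\\s*([A-Z]\\s+){19}[A-Z]", lines) & !is_row]
  if (length(hdr)) {
    aa <- strsplit(trimws(hdr[1]), "\\s+")[[1]][1:20]
    colnames(mat) <- aa
  } else {
    colnames(mat) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  }
  structure(list(domain_id = domain_id,
                 sequence = paste(res, collapse = ""),
                 matrix = mat),
            class = "pssm_profile")
}

#' Write a minimal PSI-BLAST-style ASCII PSSM
#'
#' Emits a syntactically valid ASCII PSSM (header, amino-acid column line,
#' first score block, footer) that [read_pssm_ascii()] round-trips.
#'
#' @param profile A `pssm_profile` (or list with `sequence` and `matrix`).
#' @param path Output path.
#' @export
write_pssm_ascii <- function(profile, path) {
  mat <- profile$matrix
  res <- strsplit(profile$sequence, "")[[1]]
  stopifnot(nrow(mat) == length(res), ncol(mat) == 20L)
  aa <- colnames(mat)
  if (is.null(aa)) aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ", paste(sprintf("%3s", aa), collapse = " "))),
             con)
  for (i in seq_len(nrow(mat))) {
    writeLines(sprintf("%5d %s  %s", i, res[i],
                       paste(sprintf("%3d", as.integer(round(mat[i, ]))),
                             collapse = " ")), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1337     0.3176"), con)
  invisible(path)
}

#' Read InterProScan TSV hits
#'
#' Uses column 1 (sequence id) and column 12 (InterPro accession); rows
#' with `-` in column 12 (no InterPro integration) are dropped. Hits are
#' deduplicated to distinct (domain, IPR) pairs.
#'
#' @param path Path to an InterProScan TSV file.
#' @return data.frame with columns `domain_id`, `interpro_acc`.
#' @export
read_interproscan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(lines)) {
    return(data.frame(domain_id = character(0), interpro_acc = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short)) {
    stop(sprintf("InterProScan line %d has fewer than 12 columns", short[1]))
  }
  dom <- vapply(fields, `[`, "", 1L)
  ipr <- vapply(fields, `[`, "", 12L)
  keep <- ipr != "-"
  dom <- dom[keep]; ipr <- ipr[keep]
  bad <- !grepl("^IPR\\d{6}$", ipr)
  if (any(bad)) {
    stop(sprintf("malformed InterPro accession '%s'", ipr[which(bad)[1]]))
  }
  df <- unique(data.frame(domain_id = dom, interpro_acc = ipr,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Read an InterPro2GO mapping file
#'
#' Flat mapping lines of the form
#' `InterPro:IPR000001 Kringle > GO:blood coagulation ; GO:0007596`.
#' Comment lines start with `!`.
#'
#' @param path Path to the mapping file.
#' @return Named list: IPR accession -> character vector of GO accessions.
#' @export
read_interpro2go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  m <- regmatches(lines,
                  regexec("^InterPro:(IPR\\d{6}).*;\\s*(GO:\\d{7})\\s*$",
                          lines))
  ok <- lengths(m) == 3L
  if (any(!ok)) {
    stop(sprintf("malformed InterPro2GO line: '%s'", lines[which(!ok)[1]]))
  }
  ipr <- vapply(m, `[`, "", 2L)
  go <- vapply(m, `[`, "", 3L)
  split(go, ipr)
}

#' Write an InterPro2GO mapping file
#' @param map Named list IPR -> GO accessions.
#' @param path Output path.
#' @export
write_interpro2go <- function(map, path) {
  lines <- unlist(lapply(names(map), function(ipr) {
    sprintf("InterPro:%s entry > GO:term ; %s", ipr, map[[ipr]])
  }), use.names = FALSE)
  writeLines(c("!version: synthetic", lines), path)
  invisible(path)
}

#' Write an annotation-result table
#'
#' One row per (domain, term); scores fixed at 6 decimals; rows sorted by
#' domain id then descending posterior.
#'
#' @param results data.frame as returned by [combine()] /
#'   [predict.lr_table()]: columns `domain_id`, `term`, `aspect`,
#'   `posterior`, plus any per-component score columns.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @export
write_annotations <- function(results, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  need <- c("domain_id", "term", "aspect", "posterior")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    stop(sprintf("results missing column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- results[order(results$domain_id, -results$posterior), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an annotation table written by [write_annotations()]
#' @param path Path to the TSV/CSV file.
#' @param format `"tsv"` or `"csv"`.
#' @return data.frame with numeric score columns restored.
#' @export
read_annotations <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  df
}

#' Read domain sequences from FASTA
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_domain_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(unlist(seqs, use.names = FALSE)), names(seqs))
}

#' Write domain sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_domain_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE)
  invisible(path)
}
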