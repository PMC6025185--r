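#' Configuration for the synthetic-fixture generator
#'
#' Bundles the generating parameters for a self-consistent desk-scale
#' benchmark: a random GO DAG, domains with known gold annotations, and
#' the four evidence channels (structural neighbors, InterPro hits, PSSM
#' profiles, sequence homologs) whose fidelity to the gold standard is
#' controlled by per-channel signal strengths.
#'
#' `signal` is the probability that a channel's evidence carrier (a
#' neighbor protein, an InterPro entry, a homolog, a PSSM sequence motif)
#' reflects a true gold term; `noise` the probability it picks up a random
#' spurious term; `channel_coverage` the probability a domain has any
#' evidence on a channel at all (no real evidence channel covers every
#' domain, and partial, complementary coverage is what makes integration
#' pay off).
#'
#' @param seed RNG seed; the whole bundle is deterministic given it.
#' @param n_domains,n_proteins,n_terms Universe sizes (n_terms split
#'   across the three aspects; must be >= 9).
#' @param dag_depth Levels per aspect below the root.
#' @param gold_per_aspect Gold leaf terms drawn per domain and aspect.
#' @param signal Named numeric: channel signal strengths in \[0,1\] for
#'   `str`, `ipr`, `pssm`, `seq`.
#' @param noise Spurious-term rate in \[0,1\].
#' @param channel_coverage Per-channel probability a domain has evidence.
#' @param neighbors_per_domain,ipr_per_domain,homologs_per_domain Evidence
#'   carriers per covered domain.
#' @param pssm_length Residues per generated PSSM profile.
#' @param acc_lag Auto-covariance lag the bundle is meant to be scored
#'   with (recorded in the manifest).
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_domains = 60L, n_proteins = 150L,
                           n_terms = 60L, dag_depth = 4L,
                           gold_per_aspect = 2L,
                           signal = c(str = 0.9, ipr = 0.9,
                                      pssm = 0.9, seq = 0.9),
                           noise = 0.1, channel_coverage = 0.7,
                           neighbors_per_domain = 20L,
                           ipr_per_domain = 4L,
                           homologs_per_domain = 12L,
                           pssm_length = 60L, acc_lag = 10L) {
  if (n_terms < 9L) stop("n_terms must be at least 9 (3 per aspect)")
  stopifnot(all(signal >= 0 & signal <= 1), noise >= 0, noise <= 1,
            channel_coverage >= 0, channel_coverage <= 1,
            pssm_length > acc_lag)
  if (!all(c("str", "ipr", "pssm", "seq") %in% names(signal))) {
    stop("signal must carry names str, ipr, pssm, seq")
  }
  structure(list(seed = seed, n_domains = n_domains,
                 n_proteins = n_proteins, n_terms = n_terms,
                 dag_depth = dag_depth, gold_per_aspect = gold_per_aspect,
                 signal = signal, noise = noise,
                 channel_coverage = channel_coverage,
                 neighbors_per_domain = neighbors_per_domain,
                 ipr_per_domain = ipr_per_domain,
                 homologs_per_domain = homologs_per_domain,
                 pssm_length = pssm_length, acc_lag = acc_lag),
            class = "fixture_config")
}

.gen_ontology_lines <- function(cfg) {
  aspects <- c("MF", "BP", "CC")
  ns <- c(MF = "molecular_function", BP = "biological_process",
          CC = "cellular_component")
  per <- diff(round(seq(0, cfg$n_terms, length.out = 4L)))
  lines <- c("format-version: 1.2", "ontology: synthetic-go", "")
  term_no <- 0L
  info <- list()
  for (ai in seq_along(aspects)) {
    a <- aspects[ai]
    n_a <- per[ai]
    ids <- sprintf("GO:%07d", term_no + seq_len(n_a))
    term_no <- term_no + n_a
    # level assignment: root at level 0, rest spread over 1..dag_depth
    lev <- c(0L, sort(rep_len(seq_len(cfg$dag_depth), n_a - 1L)))
    parents <- vector("list", n_a)
    for (i in seq_len(n_a)[-1]) {
      pool <- which(lev == lev[i] - 1L)
      if (!length(pool)) pool <- 1L
      k <- min(length(pool), sample(1:2, 1L))
      parents[[i]] <- ids[sample(pool, k)]
    }
    for (i in seq_len(n_a)) {
      lines <- c(lines, "[Term]", sprintf("id: %s", ids[i]),
                 sprintf("name: synthetic term %s %d", a, i),
                 sprintf("namespace: %s", ns[a]),
                 sprintf("is_a: %s ! parent", parents[[i]]),
                 "")
    }
    info[[a]] <- list(ids = ids, level = lev)
  }
  list(lines = lines, info = info)
}

.write_gaf <- function(entities, terms, aspects, path) {
  code <- c(MF = "F", BP = "P", CC = "C")
  rows <- sprintf("DB\t%s\t%s\t\t%s\tREF\tIEA\t\t%s\t\t\tprotein\ttaxon:0\t20260101\tDB\t\t",
                  entities, entities, terms, code[aspects])
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Generate a synthetic fixture bundle
#'
#' Writes every input the annotation pipeline consumes — OBO ontology,
#' gold GAF, neighbor table, protein GAF, InterProScan TSV + InterPro2GO
#' map, ASCII PSSM files, BLAST tabular homolog hits + homolog GAF, domain
#' FASTA — into `dir`, together with a `manifest.txt` recording the
#' generating parameters. Deterministic given `config$seed`; every file
#' round-trips through the package's readers.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory `ontology`, the propagated
#'   `gold` annotation set, the per-channel covered domain ids, the
#'   designated PSSM terms, and all file `paths`.
#' @export
generate_fixtures <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  set.seed(config$seed)

  onto_gen <- .gen_ontology_lines(config)
  obo_path <- file.path(dir, "ontology.obo")
  writeLines(onto_gen$lines, obo_path)
  onto <- parse_obo(obo_path)

  aspects <- c("MF", "BP", "CC")
  nonroot <- lapply(aspects, function(a) {
    setdiff(onto$terms$id[onto$terms$aspect == a & !onto$terms$obsolete],
            unname(onto$roots))
  })
  names(nonroot) <- aspects

  domains <- sprintf("d%04da1", seq_len(config$n_domains))
  proteins <- sprintf("%04x", 4096L + seq_len(config$n_proteins))

  # gold: leaf draws per aspect, then true-path closure
  g_ent <- character(0); g_trm <- character(0)
  for (d in domains) {
    for (a in aspects) {
      k <- min(config$gold_per_aspect, length(nonroot[[a]]))
      g_ent <- c(g_ent, rep(d, k))
      g_trm <- c(g_trm, sample(nonroot[[a]], k))
    }
  }
  gold_direct <- annotation_set(g_ent, g_trm, onto)
  gold <- propagate(gold_direct, onto)
  gold_leaf_by_dom <- split(gold_direct$term, gold_direct$entity)
  all_nonroot <- unlist(nonroot, use.names = FALSE)

  gaf_gold <- file.path(dir, "gold.gaf")
  .write_gaf(gold_direct$entity, gold_direct$term, gold_direct$aspect,
             gaf_gold)

  covered <- lapply(c(str = 1, ipr = 2, pssm = 3, seq = 4), function(i) {
    domains[stats::runif(config$n_domains) < config$channel_coverage]
  })

  ## structural channel -------------------------------------------------
  nb_dom <- character(0); nb_prot <- character(0); nb_psd <- numeric(0)
  prot_terms <- stats::setNames(vector("list", config$n_proteins), proteins)
  for (d in covered$str) {
    nbrs <- sample(proteins, min(config$neighbors_per_domain,
                                 config$n_proteins))
    nb_dom <- c(nb_dom, rep(d, length(nbrs)))
    nb_prot <- c(nb_prot, nbrs)
    nb_psd <- c(nb_psd, round(stats::runif(length(nbrs), 0.01, 0.099), 4))
    gl <- gold_leaf_by_dom[[d]]
    for (p in nbrs) {
      inherit <- gl[stats::runif(length(gl)) < config$signal["str"]]
      n_noise <- stats::rbinom(1L, 2L, config$noise)
      spurious <- if (n_noise > 0) sample(all_nonroot, n_noise) else character(0)
      prot_terms[[p]] <- unique(c(prot_terms[[p]], inherit, spurious))
    }
  }
  # decoy rows above the PSD threshold exercise the neighbor filter
  n_decoy <- max(1L, round(0.1 * length(nb_dom)))
  if (length(covered$str)) {
    nb_dom <- c(nb_dom, sample(covered$str, n_decoy, replace = TRUE))
    nb_prot <- c(nb_prot, sample(proteins, n_decoy, replace = TRUE))
    nb_psd <- c(nb_psd, round(stats::runif(n_decoy, 0.1, 0.5), 4))
  }
  nb_path <- file.path(dir, "neighbors.tsv")
  write_neighbor_table(data.frame(domain_id = nb_dom, protein_id = nb_prot,
                                  psd = nb_psd), nb_path)
  pt <- prot_terms[lengths(prot_terms) > 0]
  prot_gaf <- file.path(dir, "protein_annotations.gaf")
  pe <- rep(names(pt), lengths(pt)); pv <- unlist(pt, use.names = FALSE)
  .write_gaf(pe, pv, onto$terms[pv, "aspect"], prot_gaf)

  ## InterPro channel ---------------------------------------------------
  ips_rows <- character(0)
  i2g <- list()
  ipr_no <- 0L
  for (d in covered$ipr) {
    iprs <- sprintf("IPR%06d", ipr_no + seq_len(config$ipr_per_domain))
    ipr_no <- ipr_no + config$ipr_per_domain
    gl <- gold_leaf_by_dom[[d]]
    for (ip in iprs) {
      carry <- gl[stats::runif(length(gl)) < config$signal["ipr"]]
      n_noise <- stats::rbinom(1L, 1L, config$noise)
      spurious <- if (n_noise > 0) sample(all_nonroot, n_noise) else character(0)
      gos <- unique(c(carry, spurious))
      if (length(gos)) i2g[[ip]] <- gos
      ips_rows <- c(ips_rows, sprintf(
        "%s\tmd5\t%d\tPANTHER\tSIG\tsignature\t1\t%d\t1e-10\tT\t01-01-2026\t%s\tentry name",
        d, config$pssm_length, config$pssm_length, ip))
    }
  }
  ips_path <- file.path(dir, "interproscan.tsv")
  writeLines(ips_rows, ips_path)
  i2g_path <- file.path(dir, "interpro2go.txt")
  write_interpro2go(i2g, i2g_path)

  ## PSSM channel -------------------------------------------------------
  # designate classifier terms: frequent enough on both sides of the split
  prop_counts <- table(gold$term[!gold$term %in% unname(onto$roots)])
  lo <- max(12L, round(config$n_domains / 4)); hi <- config$n_domains - 12L
  pssm_terms <- character(0)
  for (a in aspects) {
    ca <- prop_counts[names(prop_counts) %in% nonroot[[a]]]
    ok <- ca[ca >= lo & ca <= hi]
    if (length(ok)) {
      pssm_terms <- c(pssm_terms,
                      names(sort(abs(ok - config$n_domains / 2))[
                        seq_len(min(2L, length(ok)))]))
    }
  }
  gold_key <- paste(gold$entity, gold$term)
  term_col <- stats::setNames(sample(20L, length(pssm_terms), replace = TRUE),
                              pssm_terms)
  term_period <- stats::setNames(sample(3:6, length(pssm_terms),
                                        replace = TRUE), pssm_terms)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  pssm_paths <- character(0)
  for (d in covered$pssm) {
    L <- config$pssm_length
    mat <- matrix(round(stats::rnorm(L * 20, 0, 3)), nrow = L)
    colnames(mat) <- aa20
    for (g in pssm_terms) {
      is_pos <- paste(d, g) %in% gold_key
      p_pattern <- if (is_pos) config$signal["pssm"] else config$noise
      if (stats::runif(1) < p_pattern) {
        i <- seq_len(L)
        mat[, term_col[g]] <- mat[, term_col[g]] +
          round(6 * sin(2 * pi * i / term_period[g]))
      }
    }
    prof <- structure(list(domain_id = d,
                           sequence = paste(sample(aa20, L, replace = TRUE),
                                            collapse = ""),
                           matrix = mat), class = "pssm_profile")
    p <- file.path(dir, "pssm", paste0(d, ".pssm"))
    write_pssm_ascii(prof, p)
    pssm_paths <- c(pssm_paths, p)
  }

  ## homolog channel ----------------------------------------------------
  bl_rows <- character(0)
  hom_terms <- list()
  hom_no <- 0L
  for (d in covered$seq) {
    homs <- sprintf("H%05d", hom_no + seq_len(config$homologs_per_domain))
    hom_no <- hom_no + config$homologs_per_domain
    ev <- 10^stats::runif(length(homs), -30, -2)
    cov <- round(stats::runif(length(homs), 0.65, 1), 3)
    # a few sub-threshold decoys that filter_homologs must drop
    low <- stats::runif(length(homs)) < 0.15
    cov[low] <- round(stats::runif(sum(low), 0.2, 0.6), 3)
    gl <- gold_leaf_by_dom[[d]]
    for (j in seq_along(homs)) {
      carry <- gl[stats::runif(length(gl)) < config$signal["seq"]]
      n_noise <- stats::rbinom(1L, 2L, config$noise)
      spurious <- if (n_noise > 0) sample(all_nonroot, n_noise) else character(0)
      hom_terms[[homs[j]]] <- unique(c(carry, spurious))
      bl_rows <- c(bl_rows, sprintf(
        "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f\t%d",
        d, homs[j], stats::runif(1, 30, 95), config$pssm_length, 5L, 1L,
        1L, config$pssm_length, 1L, config$pssm_length, ev[j],
        stats::runif(1, 50, 300), as.integer(round(cov[j] * 100))))
    }
  }
  blast_path <- file.path(dir, "blast.tsv")
  writeLines(bl_rows, blast_path)
  ht <- hom_terms[lengths(hom_terms) > 0]
  hom_gaf <- file.path(dir, "homolog_annotations.gaf")
  he <- rep(names(ht), lengths(ht)); hv <- unlist(ht, use.names = FALSE)
  .write_gaf(he, hv, onto$terms[hv, "aspect"], hom_gaf)

  ## domain sequences + manifest ----------------------------------------
  seqs <- vapply(domains, function(d) {
    paste(sample(aa20, config$pssm_length, replace = TRUE), collapse = "")
  }, "")
  fasta_path <- file.path(dir, "domains.fasta")
  write_domain_fasta(seqs, fasta_path)

  manifest_path <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("seed=%d", config$seed),
    sprintf("n_domains=%d", config$n_domains),
    sprintf("n_proteins=%d", config$n_proteins),
    sprintf("n_terms=%d", config$n_terms),
    sprintf("signal_str=%g", config$signal["str"]),
    sprintf("signal_ipr=%g", config$signal["ipr"]),
    sprintf("signal_pssm=%g", config$signal["pssm"]),
    sprintf("signal_seq=%g", config$signal["seq"]),
    sprintf("noise=%g", config$noise),
    sprintf("channel_coverage=%g", config$channel_coverage),
    sprintf("acc_lag=%d", config$acc_lag),
    sprintf("pssm_terms=%s", paste(pssm_terms, collapse = ","))),
    manifest_path)

  invisible(list(ontology = onto, gold = gold, gold_direct = gold_direct,
                 domains = domains, covered = covered,
                 pssm_terms = pssm_terms, config = config,
                 paths = list(obo = obo_path, gold_gaf = gaf_gold,
                              neighbors = nb_path, protein_gaf = prot_gaf,
                              interproscan = ips_path,
                              interpro2go = i2g_path,
                              pssm_dir = file.path(dir, "pssm"),
                              pssm = pssm_paths, blast = blast_path,
                              homolog_gaf = hom_gaf, fasta = fasta_path,
                              manifest = manifest_path)))
}

#' Simulate binned calibration scores with known per-bin positive rates
#'
#' Utility for validating the likelihood-ratio estimator: draws n
#' (score, label) pairs where the score's bin is chosen uniformly and the
#' label is Bernoulli with the bin's positive rate, so the analytic LR per
#' bin is `(q_b / (1 - q_b)) / (p / (1 - p))` with p the mean positive
#' rate.
#'
#' @param n Number of pairs.
#' @param rates Numeric vector of per-bin positive rates (length = bins).
#' @return data.frame with columns `score`, `label`, `bin`.
#' @export
simulate_binned_scores <- function(n, rates) {
  bins <- length(rates)
  b <- sample.int(bins, n, replace = TRUE)
  score <- (b - 1 + stats::runif(n)) / bins
  score[score >= 1] <- 1 - 1e-12
  label <- stats::runif(n) < rates[b]
  data.frame(score = score, label = label, bin = b)
}
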