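#' Configuration of the synthetic benchmark generator
#'
#' Defines the study conditions the generator emulates: a nested host
#' taxonomy (phyla / genera / strains), host genomes with genus-specific
#' sequence composition, training phages each paired with one host
#' strain and carrying a genuine shared fragment of that host's genome
#' (the prophage-like signal that drives phage-host alignment and gives
#' the k-mer classifier something to learn), test phages derived from
#' training phages by point mutation (the signal that drives phage-phage
#' alignment), and CRISPR arrays planted into a fraction of hosts whose
#' one spacer is a verbatim protospacer of the host's phage (the signal
#' that drives spacer matching).
#'
#' @param seed integer; every run with the same config is byte-identical.
#' @param n_phyla,genera_per_phylum,hosts_per_genus taxonomy shape
#'   (defaults 3 x 2 x 3 = 18 hosts).
#' @param host_len,phage_len genome lengths in bp.
#' @param n_train_phages,n_test_phages interaction counts (defaults 60
#'   and 40).
#' @param shared_fragment_len bases copied host -> phage.
#' @param test_mutation_rate per-base substitution probability applied
#'   to a training phage to derive a test phage.
#' @param spacer_rate fraction of hosts given a CRISPR array.
#' @param planted_repeat_len,planted_spacer_len CRISPR array geometry
#'   (3 repeat copies, 2 spacers; the second spacer is the protospacer).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 42L, n_phyla = 3L, genera_per_phylum = 2L,
                       hosts_per_genus = 3L, host_len = 20000L,
                       phage_len = 5000L, n_train_phages = 60L,
                       n_test_phages = 40L, shared_fragment_len = 800L,
                       test_mutation_rate = 0.05, spacer_rate = 0.5,
                       planted_repeat_len = 28L,
                       planted_spacer_len = 32L) {
  cfg <- list(seed = as.integer(seed), n_phyla = as.integer(n_phyla),
              genera_per_phylum = as.integer(genera_per_phylum),
              hosts_per_genus = as.integer(hosts_per_genus),
              host_len = as.integer(host_len),
              phage_len = as.integer(phage_len),
              n_train_phages = as.integer(n_train_phages),
              n_test_phages = as.integer(n_test_phages),
              shared_fragment_len = as.integer(shared_fragment_len),
              test_mutation_rate = test_mutation_rate,
              spacer_rate = spacer_rate,
              planted_repeat_len = as.integer(planted_repeat_len),
              planted_spacer_len = as.integer(planted_spacer_len))
  stopifnot(cfg$n_phyla >= 1, cfg$genera_per_phylum >= 1,
            cfg$hosts_per_genus >= 1,
            cfg$test_mutation_rate >= 0, cfg$test_mutation_rate <= 1,
            cfg$spacer_rate >= 0, cfg$spacer_rate <= 1)
  if (cfg$shared_fragment_len >= cfg$phage_len ||
      cfg$shared_fragment_len >= cfg$host_len)
    stop("shared fragment longer than a genome")
  if (cfg$n_test_phages > cfg$n_train_phages)
    stop("more test phages than training parents")
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# Uniform iid nucleotide string.
#' @keywords internal
rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE),
                              collapse = "")

# First-order Markov nucleotide string with transition matrix P (rows
# sum to 1). Genus-specific transition structure is what gives the
# composition-corrected k-mer features a learnable signal: the
# modified-frequency transform removes independent-base composition by
# construction, so marginal base frequencies alone carry no information.
#' @keywords internal
markov_seq <- function(L, P) {
  cum <- t(apply(P, 1L, cumsum))
  u <- runif(L)
  out <- integer(L)
  out[1L] <- sample.int(4L, 1L)
  for (i in 2L:L)
    out[i] <- findInterval(u[i], cum[out[i - 1L], ]) + 1L
  paste(BASES[out], collapse = "")
}

# Random row-stochastic 4x4 matrix, rows drawn from a Dirichlet.
#' @keywords internal
rand_transitions <- function(shape = 3) {
  P <- matrix(rgamma(16L, shape = shape), 4L, 4L)
  P / rowSums(P)
}

#' Mutate a nucleotide sequence by point substitution
#'
#' Each position is independently substituted with probability
#' \code{rate}; a substituted base is drawn uniformly from the three
#' other bases, so \code{rate = 1} leaves no position unchanged and
#' \code{rate = 0} is the identity.
#'
#' @param seq nucleotide string.
#' @param rate per-base substitution probability in [0,1].
#' @param seed optional integer seed for a deterministic mutation.
#' @return the mutated string, with attribute \code{"n_substitutions"}.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(toupper(as.character(seq)), "")[[1]]
  hit <- which(runif(length(v)) < rate & v %in% BASES)
  for (i in hit)
    v[i] <- sample(setdiff(BASES, v[i]), 1L)
  structure(paste(v, collapse = ""), n_substitutions = length(hit))
}

#' Simulate a complete benchmark bundle
#'
#' Deterministic in \code{cfg$seed}. Produces a validated reference
#' bundle (host genomes with a nested taxonomy, training phages with
#' planted host fragments, training interactions), a held-out test
#' interaction table with the test phage genomes, and a truth log
#' recording every planted signal (fragment coordinates, test-phage
#' parentage and substitution counts, CRISPR array coordinates and
#' protospacer provenance).
#'
#' The planted CRISPR arrays keep the single column flanking each side
#' of the repeat copies non-unanimous across copies, so the planted
#' boundaries are the unique stopping point of consensus extension and
#' detection can be checked against exact coordinates.
#'
#' @param cfg a \code{"sim_config"}.
#' @return list with elements \code{bundle} (a \code{"ref_bundle"}),
#'   \code{test} (interaction data.frame), \code{test_phages}
#'   (\link[Biostrings]{DNAStringSet}) and \code{truth_log} (list).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_genera <- cfg$n_phyla * cfg$genera_per_phylum
  M <- n_genera * cfg$hosts_per_genus

  # ---- taxonomy: nested ranks; families group genera in pairs within
  # a phylum; order/class are 1:1 with phylum ----
  host_ids <- sprintf("h%03d", seq_len(M))
  g_idx <- rep(seq_len(n_genera), each = cfg$hosts_per_genus)
  p_idx <- rep(seq_len(cfg$n_phyla),
               each = cfg$genera_per_phylum * cfg$hosts_per_genus)
  g_in_p <- rep(rep(seq_len(cfg$genera_per_phylum),
                    each = cfg$hosts_per_genus), cfg$n_phyla)
  taxonomy <- data.frame(
    host_id = host_ids,
    strain = host_ids,
    species = sprintf("S%s", sub("^h", "", host_ids)),
    genus = sprintf("G%d.%d", p_idx, g_in_p),
    family = sprintf("F%d.%d", p_idx, ceiling(g_in_p / 2)),
    order = sprintf("O%d", p_idx),
    class = sprintf("C%d", p_idx),
    phylum = sprintf("P%d", p_idx),
    stringsAsFactors = FALSE)

  # ---- host genomes: genus-specific first-order Markov composition --
  trans <- lapply(seq_len(n_genera), function(i) rand_transitions())
  hosts <- vapply(seq_len(M),
                  function(i) markov_seq(cfg$host_len, trans[[g_idx[i]]]),
                  character(1))
  names(hosts) <- host_ids

  # ---- training phages: genus background + a fragment copied from
  # the paired host ----
  phage_ids <- sprintf("p%03d", seq_len(cfg$n_train_phages))
  phage_host <- host_ids[(seq_len(cfg$n_train_phages) - 1L) %% M + 1L]
  frag_log <- data.frame(phage_id = phage_ids, host_id = phage_host,
                         host_start = NA_integer_,
                         phage_start = NA_integer_,
                         len = cfg$shared_fragment_len,
                         stringsAsFactors = FALSE)
  host_used <- setNames(vector("list", M), host_ids)  # reserved spans
  phages <- character(cfg$n_train_phages)
  for (j in seq_len(cfg$n_train_phages)) {
    h <- phage_host[j]
    bg <- markov_seq(cfg$phage_len, trans[[g_idx[match(h, host_ids)]]])
    hstart <- sample.int(cfg$host_len - cfg$shared_fragment_len, 1L)
    pstart <- sample.int(cfg$phage_len - cfg$shared_fragment_len, 1L)
    frag <- substr(hosts[[h]], hstart,
                   hstart + cfg$shared_fragment_len - 1L)
    substr(bg, pstart, pstart + cfg$shared_fragment_len - 1L) <- frag
    phages[j] <- bg
    frag_log$host_start[j] <- hstart
    frag_log$phage_start[j] <- pstart
    host_used[[h]] <- c(host_used[[h]],
                        list(c(hstart, hstart +
                                 cfg$shared_fragment_len - 1L)))
  }
  names(phages) <- phage_ids

  # ---- CRISPR arrays planted into a fraction of hosts ----
  n_crispr <- round(cfg$spacer_rate * M)
  crispr_hosts <- if (n_crispr > 0) sort(sample(host_ids, n_crispr))
                  else character(0)
  arrays <- list()
  for (h in crispr_hosts) {
    ph_of_h <- phage_ids[phage_host == h]
    if (!length(ph_of_h)) next
    donor <- sort(ph_of_h)[1L]
    arr <- plant_array(hosts[[h]], phages[[donor]], cfg,
                       avoid = host_used[[h]])
    if (is.null(arr)) next
    hosts[[h]] <- arr$genome
    arrays[[length(arrays) + 1L]] <- c(list(host_id = h,
                                            protospacer_phage = donor),
                                       arr[names(arr) != "genome"])
  }

  # ---- test phages: mutated copies of sampled training phages ----
  parents <- sort(sample(phage_ids, cfg$n_test_phages))
  test_ids <- sprintf("t%03d", seq_len(cfg$n_test_phages))
  test_seqs <- character(cfg$n_test_phages)
  nsub <- integer(cfg$n_test_phages)
  for (j in seq_len(cfg$n_test_phages)) {
    m <- mutate_sequence(phages[[parents[j]]], cfg$test_mutation_rate)
    test_seqs[j] <- m
    nsub[j] <- attr(m, "n_substitutions")
  }
  names(test_seqs) <- test_ids

  bundle <- new_bundle(Biostrings::DNAStringSet(phages),
                       Biostrings::DNAStringSet(hosts),
                       taxonomy,
                       data.frame(phage_id = phage_ids,
                                  host_id = phage_host,
                                  stringsAsFactors = FALSE))
  test <- data.frame(phage_id = test_ids,
                     host_id = phage_host[match(parents, phage_ids)],
                     stringsAsFactors = FALSE)
  attr(test, "role") <- "testing"
  truth_log <- list(config = unclass(cfg), fragments = frag_log,
                    arrays = arrays,
                    tests = data.frame(test_id = test_ids,
                                       parent = parents,
                                       n_substitutions = nsub,
                                       stringsAsFactors = FALSE))
  list(bundle = bundle, test = test,
       test_phages = Biostrings::DNAStringSet(test_seqs),
       truth_log = truth_log)
}

# Build one R-S1-R-S2-R array (3 repeat copies, 2 spacers; S2 is a
# verbatim protospacer from the donor phage) and splice it into the
# host genome, replacing a slice of equal length that avoids reserved
# spans. Keeps the flanking column on each side of the repeat copies
# non-unanimous. Returns NULL when no position is free.
#' @keywords internal
plant_array <- function(genome, donor_phage, cfg, avoid = list()) {
  rl <- cfg$planted_repeat_len; sl <- cfg$planted_spacer_len
  total <- 3L * rl + 2L * sl
  L <- nchar(genome)
  for (try in 1:50) {
    pos <- sample.int(L - total - 2L, 1L) + 1L  # leave 1 bp flanks
    ok <- all(vapply(avoid, function(iv)
      pos + total - 1L < iv[1] || pos > iv[2], logical(1)))
    if (ok) break
    pos <- NA_integer_
  }
  if (is.na(pos)) return(NULL)
  rep_seq <- rand_seq(rl)
  s1 <- rand_seq(sl)
  pp_start <- sample.int(cfg$phage_len - sl, 1L)
  s2 <- substr(donor_phage, pp_start, pp_start + sl - 1L)
  pre <- substr(genome, pos - 1L, pos - 1L)
  post <- substr(genome, pos + total, pos + total)
  # Keep the flank base of adjacent copies distinct on both sides
  # (pre vs S1-last, S1-last vs S2-last; S1-first vs S2-first,
  # S2-first vs post): a shared flank base lets seed extension absorb
  # the column into the repeat and shift the boundary. Only S1 and the
  # host flank are adjusted; the protospacer S2 stays verbatim.
  substr(s1, sl, sl) <- setdiff(BASES, c(pre, substr(s2, sl, sl)))[1L]
  substr(s1, 1L, 1L) <- setdiff(BASES, substr(s2, 1L, 1L))[1L]
  if (post == substr(s2, 1L, 1L))
    substr(genome, pos + total, pos + total) <- setdiff(BASES, post)[1L]
  # and keep the second and third columns beyond each boundary
  # non-unanimous, so mismatch bridging (which can span two columns)
  # cannot carry extension across the boundary
  for (j in c(sl - 1L, sl - 2L))
    substr(s1, j, j) <- setdiff(BASES, substr(s2, j, j))[1L]
  for (j in 2:3)
    substr(s1, j, j) <- setdiff(BASES, substr(s2, j, j))[1L]
  arr <- paste0(rep_seq, s1, rep_seq, s2, rep_seq)
  substr(genome, pos, pos + total - 1L) <- arr
  list(genome = genome,
       start = pos - 1L, end = pos + total - 1L,   # 0-based half-open
       repeat_starts = pos - 1L + c(0L, rl + sl, 2L * (rl + sl)),
       repeat_len = rl, repeat_seq = rep_seq,
       spacers = c(s1, s2), protospacer_start = pp_start - 1L)
}
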