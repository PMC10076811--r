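# Fixture builders and independent oracles. Oracles are deliberately
# naive (window enumeration, literal formulas, brute-force scans) so
# they stay independent of the implementation paths they check.

BASES4 <- c("A", "C", "G", "T")

rseq <- function(n) paste(sample(BASES4, n, TRUE), collapse = "")

dss <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

# ---- oracle: enumerate every overlapping window ----------------------
brute_count_kmers <- function(seq, k) {
  kmers <- sort(apply(expand.grid(rep(list(BASES4), k)), 1,
                      paste, collapse = ""))
  out <- setNames(integer(4^k), kmers)
  n <- nchar(seq)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (w %in% kmers) out[w] <- out[w] + 1L
  }
  out
}

# ---- oracle: literal per-k-mer application of the correction --------
brute_modified_frequency <- function(seq, k) {
  fo <- brute_count_kmers(seq, k)
  ch <- strsplit(seq, "")[[1]]
  ch <- ch[ch %in% BASES4]
  L <- length(ch)
  p <- setNames(tabulate(match(ch, BASES4), 4) / L, BASES4)
  vapply(names(fo), function(w) {
    pw <- prod(p[strsplit(w, "")[[1]]])
    fo[[w]] - pw * (L - (k - 1))
  }, numeric(1))
}

# ---- oracle: any exact shared word between two sequences, on either
# strand (the external aligner searches both strands) ----------------
revcomp <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                               collapse = ""))

longest_shared_word <- function(a, b, w) {
  words <- function(x) substring(x, seq_len(nchar(x) - w + 1),
                                 w:nchar(x))
  wa <- c(words(a), words(revcomp(a)))
  length(intersect(wa, words(b))) > 0
}

# ---- oracle: any seed chain that could nominate a CRISPR array ------
# three same 8-mers with consecutive gaps in [38, 86]
brute_has_chain <- function(seq) {
  w <- 8
  words <- substring(seq, seq_len(nchar(seq) - w + 1),
                     w:nchar(seq))
  pos <- split(seq_along(words), words)
  for (pp in pos) {
    if (length(pp) < 3) next
    for (i in seq_along(pp)) for (j in seq_along(pp)) {
      d1 <- pp[j] - pp[i]
      if (d1 < 38 || d1 > 86) next
      for (l in seq_along(pp)) {
        d2 <- pp[l] - pp[j]
        if (d2 >= 38 && d2 <= 86) return(TRUE)
      }
    }
  }
  FALSE
}

# ---- tiny bundle written to disk (3 phages / 2 hosts / 3 pairs) -----
write_tiny_bundle_files <- function(dir, host_dup_id = FALSE,
                                    bad_host_ref = FALSE) {
  set.seed(404)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h1 <- rseq(600); h2 <- rseq(600)
  p1 <- rseq(300); p2 <- rseq(300); p3 <- rseq(300)
  substr(p1, 50, 149) <- substr(h1, 101, 200)   # planted fragment
  writeLines(c(">p1", p1, ">p2", p2, ">p3", p3),
             file.path(dir, "phages.fasta"))
  h2_id <- if (host_dup_id) "h1" else "h2"
  writeLines(c(">h1 some description", h1, paste0(">", h2_id), h2),
             file.path(dir, "hosts.fasta"))
  writeLines(c(paste(c("host_id", "strain", "species", "genus",
                       "family", "order", "class", "phylum"),
                     collapse = "\t"),
               paste(c("h1", "h1", "s1", "gA", "fA", "oA", "cA", "pA"),
                     collapse = "\t"),
               paste(c("h2", "h2", "s2", "gB", "fB", "oA", "cA", "pA"),
                     collapse = "\t")),
             file.path(dir, "taxonomy.tsv"))
  hx <- if (bad_host_ref) "hX" else "h2"
  writeLines(c("phage_id\thost_id", "p1\th1", "p2\th2",
               paste0("p3\t", hx)),
             file.path(dir, "interactions.tsv"))
  dir
}

load_tiny_bundle <- function(dir = tempfile("bundle")) {
  write_tiny_bundle_files(dir)
  load_bundle(file.path(dir, "phages.fasta"),
              file.path(dir, "hosts.fasta"),
              file.path(dir, "taxonomy.tsv"),
              file.path(dir, "interactions.tsv"))
}

# ---- separable two-host bundle: disjoint hexamer vocabularies -------
# Host A phages are concatenations of motifs over {A,C}; host B phages
# over {G,T}; the two classes cannot overlap in k-mer space.
make_separable_bundle <- function(n_per_class = 6, phage_len = 600,
                                  seed = 11) {
  set.seed(seed)
  gen <- function(alph, n) paste(sample(alph, n, TRUE), collapse = "")
  phages <- c(
    setNames(lapply(seq_len(n_per_class),
                    function(i) gen(c("A", "C"), phage_len)),
             sprintf("pA%02d", seq_len(n_per_class))),
    setNames(lapply(seq_len(n_per_class),
                    function(i) gen(c("G", "T"), phage_len)),
             sprintf("pB%02d", seq_len(n_per_class))))
  hosts <- c(hA = gen(c("A", "C"), 1500), hB = gen(c("G", "T"), 1500))
  taxonomy <- data.frame(
    host_id = c("hA", "hB"), strain = c("hA", "hB"),
    species = c("sA", "sB"), genus = c("gA", "gB"),
    family = c("fA", "fB"), order = c("oA", "oB"),
    class = c("cA", "cB"), phylum = c("pA", "pB"),
    stringsAsFactors = FALSE)
  training <- data.frame(
    phage_id = names(phages),
    host_id = rep(c("hA", "hB"), each = n_per_class),
    stringsAsFactors = FALSE)
  new_bundle(Biostrings::DNAStringSet(unlist(phages)),
             Biostrings::DNAStringSet(hosts), taxonomy, training)
}

# ---- planted CRISPR array fixture -----------------------------------
# Builds a genome with one R-S1-R-S2-R array at a known position.
# Interior mutations (optional) are placed at columns 3..(rl-2) of
# chosen copies so boundary columns stay intact. Flank guard columns
# are made non-unanimous as in the package generator, so the planted
# coordinates are the unique consensus boundaries.
plant_fixture_array <- function(genome_len = 3000, rl = 28, sl = 32,
                                n_mut_per_copy = 0, seed = 1) {
  set.seed(seed)
  g <- rseq(genome_len)
  r0 <- rseq(rl)
  copies <- rep(r0, 3)
  if (n_mut_per_copy > 0) {
    # Mutation placement respects what a seed-based detector can see:
    # distinct columns across copies (a doubly-hit column flips the
    # majority consensus against the clean copy), no 3 consecutive
    # mutated columns (boundary-vs-degeneracy becomes ambiguous), and
    # some adjacent copy pair keeps an intact seed word of length 8.
    repeat {
      cols <- sort(sample(3:(rl - 2), 3 * n_mut_per_copy))
      if (any(diff(cols, lag = 2) == 2)) next
      by_copy <- split(sample(cols), rep(1:3, each = n_mut_per_copy))
      seed_ok <- function(a, b) {
        bad <- sort(unique(c(by_copy[[a]], by_copy[[b]])))
        any(diff(c(0, bad, rl + 1)) > 8)   # an 8-run survives
      }
      if (seed_ok(1, 2) || seed_ok(2, 3)) break
    }
    for (k in 1:3) {
      for (i in by_copy[[k]]) {
        b <- substr(copies[k], i, i)
        substr(copies[k], i, i) <- sample(setdiff(BASES4, b), 1)
      }
    }
  }
  s1 <- rseq(sl); s2 <- rseq(sl)
  total <- 3 * rl + 2 * sl
  pos <- sample(2:(genome_len - total - 1), 1)
  pre <- substr(g, pos - 1, pos - 1)
  post <- substr(g, pos + total, pos + total)
  substr(s1, sl, sl) <- setdiff(BASES4, c(pre, substr(s2, sl, sl)))[1]
  substr(s1, 1, 1) <- setdiff(BASES4, substr(s2, 1, 1))[1]
  if (post == substr(s2, 1, 1))
    substr(g, pos + total, pos + total) <- setdiff(BASES4, post)[1]
  for (j in c(sl - 1, sl - 2))
    substr(s1, j, j) <- setdiff(BASES4, substr(s2, j, j))[1]
  for (j in 2:3)
    substr(s1, j, j) <- setdiff(BASES4, substr(s2, j, j))[1]
  arr <- paste0(copies[1], s1, copies[2], s2, copies[3])
  substr(g, pos, pos + total - 1) <- arr
  list(genome = g, start = pos - 1L, end = pos + total - 1L,
       repeat_seq = r0, spacers = c(s1, s2),
       repeat_starts = pos - 1L + c(0L, rl + sl, 2L * (rl + sl)),
       repeat_len = rl)
}
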