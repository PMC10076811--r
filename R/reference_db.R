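#' Read and validate a genome FASTA
#'
#' Genomes are nucleotide sequences over the alphabet \{A,C,G,T,N\}.
#' Sequences are upper-cased on ingest; any other character is an error
#' (downstream k-mer math assumes the 4-letter alphabet, so an explicit
#' failure beats silent corruption). Record IDs must be unique; the ID is
#' the first whitespace-delimited token of the FASTA header.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
read_genomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_genomes(seqs, label = basename(path))
}

#' @keywords internal
validate_genomes <- function(seqs, label = "genomes") {
  if (length(seqs) == 0L) stop(label, ": no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop(label, ": empty sequence ID")
  if (anyDuplicated(ids))
    stop(label, ": duplicate ID: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  freq <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE]) > 0
  if (any(bad))
    stop(label, ": characters outside {A,C,G,T,N} in: ",
         paste(ids[bad], collapse = ", "))
  seqs
}

#' Read a host taxonomy table
#'
#' Tab-separated columns: host_id, strain, species, genus, family, order,
#' class, phylum. Unknown names are encoded with the reserved token
#' \code{"NA"}; the phylum must be known. A missing lower rank stays
#' unknown, it is never filled from a neighbouring rank.
#'
#' @param path path to the TSV (with header).
#' @return a data.frame with the eight columns above.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tax <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", na.strings = NULL,
                    quote = "", comment.char = "")
  need <- c("host_id", TAX_RANKS)
  if (!all(need %in% names(tax)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  tax <- tax[, need]
  for (r in TAX_RANKS) {
    v <- tax[[r]]
    v[is.na(v) | !nzchar(v)] <- NA_TOKEN
    tax[[r]] <- v
  }
  if (anyDuplicated(tax$host_id))
    stop("taxonomy: duplicate host_id")
  if (any(tax$phylum == NA_TOKEN))
    stop("taxonomy: phylum must be known for every host")
  tax
}

#' Read a phage-host interaction table
#'
#' Tab-separated columns: phage_id, host_id.
#'
#' @param path path to the TSV (with header).
#' @param role \code{"training"} or \code{"testing"}; in training each
#'   phage must map to exactly one host strain.
#' @return a data.frame with columns phage_id, host_id and a
#'   \code{"role"} attribute.
#' @export
read_interactions <- function(path, role = c("training", "testing")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "", comment.char = "")
  if (!all(c("phage_id", "host_id") %in% names(tab)))
    stop("interactions must have columns phage_id, host_id")
  tab <- tab[, c("phage_id", "host_id")]
  if (role == "training" && anyDuplicated(tab$phage_id))
    stop("training interactions: phage mapped to more than one host")
  attr(tab, "role") <- role
  tab
}

#' Load a reference bundle
#'
#' A bundle holds everything the predictors consult: the reference phage
#' genomes with known hosts, the M reference host genomes, the host
#' taxonomy, and the training interaction table. Referential integrity is
#' enforced: every interaction must resolve to loaded genomes, and every
#' host must have a lineage. The host ordering is the first-appearance
#' order in the host FASTA and is fixed for the life of the bundle; all
#' per-host score vectors index by it.
#'
#' @param phage_fasta,host_fasta FASTA paths for phage and host genomes.
#' @param taxonomy_tsv path to the host taxonomy TSV
#'   (see \code{\link{read_taxonomy}}).
#' @param interactions_tsv path to the training interaction TSV.
#' @return an object of class \code{"ref_bundle"}: a list with elements
#'   \code{phages}, \code{hosts} (DNAStringSets), \code{taxonomy},
#'   \code{training} (data.frames), \code{host_ids} and
#'   \code{host_checksum}.
#' @export
load_bundle <- function(phage_fasta, host_fasta, taxonomy_tsv,
                        interactions_tsv) {
  phages <- read_genomes(phage_fasta)
  hosts  <- read_genomes(host_fasta)
  taxonomy <- read_taxonomy(taxonomy_tsv)
  training <- read_interactions(interactions_tsv, role = "training")
  new_bundle(phages, hosts, taxonomy, training)
}

#' Assemble a reference bundle from in-memory components
#'
#' @param phages,hosts named \link[Biostrings]{DNAStringSet}s.
#' @param taxonomy taxonomy data.frame (columns as
#'   \code{\link{read_taxonomy}}).
#' @param training training interaction data.frame.
#' @return a \code{"ref_bundle"}; see \code{\link{load_bundle}}.
#' @export
new_bundle <- function(phages, hosts, taxonomy, training) {
  phages <- validate_genomes(phages, "phages")
  hosts  <- validate_genomes(hosts, "hosts")
  if (length(hosts) < 2L) stop("need at least 2 reference hosts")
  if (length(intersect(names(phages), names(hosts))))
    stop("IDs shared between phage and host collections")
  missing_tax <- setdiff(names(hosts), taxonomy$host_id)
  if (length(missing_tax))
    stop("host without lineage: ", paste(missing_tax, collapse = ", "))
  unk_p <- setdiff(training$phage_id, names(phages))
  if (length(unk_p))
    stop("interaction references unknown phage: ",
         paste(unk_p, collapse = ", "))
  unk_h <- setdiff(training$host_id, names(hosts))
  if (length(unk_h))
    stop("interaction references unknown host: ",
         paste(unk_h, collapse = ", "))
  if (anyDuplicated(training$phage_id))
    stop("training interactions: phage mapped to more than one host")
  structure(list(
    phages = phages,
    hosts = hosts,
    taxonomy = taxonomy,
    training = training,
    host_ids = names(hosts),
    host_checksum = id_checksum(names(hosts))
  ), class = "ref_bundle")
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle\n")
  cat("  reference phages :", length(x$phages), "\n")
  cat("  reference hosts  :", length(x$hosts), "(M)\n")
  cat("  training pairs   :", nrow(x$training), "\n")
  cat("  host genera      :",
      length(unique(host_rank(x, x$host_ids, "genus"))), "\n")
  invisible(x)
}

# md5 of the ordered ID list (one per line); used to pin host order
# across persisted models and similarity matrices.
#' @keywords internal
id_checksum <- function(ids) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(ids, f)
  unname(tools::md5sum(f))
}

# Lineage lookup: rank name(s) for host id(s); unknown rank -> NA token.
#' @keywords internal
host_rank <- function(bundle, host_id, rank) {
  tax <- if (is.data.frame(bundle)) bundle else bundle$taxonomy
  stopifnot(rank %in% TAX_RANKS)
  idx <- match(host_id, tax$host_id)
  if (anyNA(idx)) stop("unknown host ID: ",
                       paste(host_id[is.na(idx)], collapse = ", "))
  tax[[rank]][idx]
}

# Host of a training phage (first-listed pair wins if a bundle ever holds
# multi-host phages; guaranteed unique for validated training tables).
#' @keywords internal
training_host <- function(bundle, phage_id) {
  idx <- match(phage_id, bundle$training$phage_id)
  bundle$training$host_id[idx]
}

#' Persist a bundle as a directory
#'
#' Writes the two FASTA files, the two TSVs, and a JSON manifest holding
#' the ordered host-ID list and per-file md5 checksums, so that
#' load -> save -> load round-trips bit-identically and the host index
#' order is verifiable.
#'
#' @param bundle a \code{"ref_bundle"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ref_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("phages.fasta", "hosts.fasta",
                            "taxonomy.tsv", "interactions.tsv"))
  Biostrings::writeXStringSet(bundle$phages, paths[1])
  Biostrings::writeXStringSet(bundle$hosts, paths[2])
  write.table(bundle$taxonomy, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$training, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(
    host_ids = bundle$host_ids,
    host_checksum = bundle$host_checksum,
    files = as.list(setNames(unname(tools::md5sum(paths)),
                             basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a bundle persisted by \code{save_bundle}
#'
#' File checksums and the host-ID order are verified against the manifest.
#'
#' @param dir bundle directory.
#' @return a \code{"ref_bundle"}.
#' @export
load_bundle_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  for (f in names(man$files)) {
    got <- unname(tools::md5sum(file.path(dir, f)))
    if (!identical(got, man$files[[f]]))
      stop("checksum mismatch for ", f)
  }
  b <- load_bundle(file.path(dir, "phages.fasta"),
                   file.path(dir, "hosts.fasta"),
                   file.path(dir, "taxonomy.tsv"),
                   file.path(dir, "interactions.tsv"))
  if (!identical(b$host_ids, as.character(man$host_ids)))
    stop("host order changed since save")
  b
}

#' Restrict a test interaction table to genera seen in training
#'
#' Evaluating a phage whose true host genus has no representative among
#' the training hosts is not meaningful, since no predictor can name an
#' unseen genus. Pairs whose true host genus does not occur among the
#' genera of the training hosts are removed. Idempotent.
#'
#' @param test a testing interaction data.frame (phage_id, host_id); host
#'   IDs must have lineages in the bundle taxonomy.
#' @param bundle a \code{"ref_bundle"}.
#' @return the retained pairs, with attribute \code{"n_removed"}.
#' @export
filter_test_by_training_genera <- function(test, bundle) {
  train_hosts <- unique(bundle$training$host_id)
  train_genera <- unique(host_rank(bundle, train_hosts, "genus"))
  train_genera <- setdiff(train_genera, NA_TOKEN)
  test_genera <- host_rank(bundle, test$host_id, "genus")
  keep <- test_genera %in% train_genera
  out <- test[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "role") <- attr(test, "role")
  attr(out, "n_removed") <- sum(!keep)
  out
}
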