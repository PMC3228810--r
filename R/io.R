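new_locus_dataset <- function(locus_id, species_mats, space = default_space(),
                              dropped = integer(0)) {
  L <- unique(vapply(species_mats, ncol, integer(1)))
  if (length(L) != 1L) stop("species matrices must share the codon length")
  for (s in names(species_mats)) {
    m <- species_mats[[s]]
    if (is.null(rownames(m)))
      rownames(m) <- paste0(s, "_", seq_len(nrow(m)))
    storage.mode(m) <- "integer"
    species_mats[[s]] <- m
  }
  structure(list(locus_id = locus_id, species = species_mats,
                 n_codons = as.integer(L), dropped = dropped),
            class = "locus_dataset")
}

#' @export
print.locus_dataset <- function(x, ...) {
  cat("Locus ", x$locus_id, ": ", x$n_codons, " codons; ",
      paste(sprintf("%s (n=%d)", names(x$species),
                    vapply(x$species, nrow, integer(1))), collapse = ", "),
      if (length(x$dropped)) sprintf("; %d columns dropped", length(x$dropped)),
      "\n", sep = "")
  invisible(x)
}

#' Read an in-frame codon alignment
#'
#' Reads a FASTA alignment of coding sequence sampled from one or more
#' species, assigns each record to a species through the sequence-to-species
#' map, and converts it to codon states.  Codon columns containing an
#' alignment gap, an ambiguity character or a stop codon in any sequence
#' are dropped from every species (the model has no missing-data
#' mechanism); the dropped positions are recorded and reported.
#'
#' @param fasta_path path to the FASTA file.
#' @param species_map data.frame with columns `seq_id` and `species`, or
#'   the path to a two-column TSV (header `seq_id<TAB>species`).
#' @param locus_id identifier (defaults to the file name).
#' @param quiet suppress the dropped-column message.
#' @param space a [codon_space()].
#' @return a `locus_dataset`.
#' @export
read_locus <- function(fasta_path, species_map, locus_id = basename(fasta_path),
                       quiet = FALSE, space = default_space()) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("empty FASTA: ", fasta_path)
  chars <- lapply(as.character(dna), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  if (lens[1] %% 3 != 0) stop("alignment length not divisible by 3")
  if (is.character(species_map) && length(species_map) == 1L)
    species_map <- utils::read.delim(species_map, stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "species") %in% names(species_map)))
  ids <- names(chars)
  sp_of <- species_map$species[match(ids, species_map$seq_id)]
  if (anyNA(sp_of))
    stop("records absent from species map: ",
         paste(ids[is.na(sp_of)], collapse = ", "))
  L <- lens[1] %/% 3
  seqmat <- do.call(rbind, chars)
  codon_of <- function(row) {
    apply(matrix(row, nrow = 3), 2, paste, collapse = "")
  }
  cods <- t(apply(seqmat, 1, codon_of))           # nseq x L codon strings
  idx <- matrix(codon_index(cods, space), nrow(cods), L)
  bad <- which(apply(idx, 2, anyNA))
  if (length(bad) && !quiet)
    message(locus_id, ": dropped ", length(bad),
            " codon column(s) with gaps, ambiguity codes or stop codons")
  keep <- setdiff(seq_len(L), bad)
  idx <- idx[, keep, drop = FALSE]
  mats <- lapply(split(seq_along(ids), sp_of), function(rows) {
    m <- idx[rows, , drop = FALSE]
    rownames(m) <- ids[rows]
    m
  })
  if (any(vapply(mats, nrow, integer(1)) == 0L)) stop("empty species")
  new_locus_dataset(locus_id, mats, space, dropped = bad)
}

#' Write a locus dataset as FASTA
#'
#' @param locus a `locus_dataset`.
#' @param path output FASTA path.
#' @param space a [codon_space()].
#' @return `path`, invisibly.
#' @export
write_locus <- function(locus, path, space = default_space()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in names(locus$species)) {
    m <- locus$species[[s]]
    for (i in seq_len(nrow(m))) {
      writeLines(paste0(">", rownames(m)[i]), con)
      writeLines(paste(space$codons[m[i, ]], collapse = ""), con)
    }
  }
  invisible(path)
}

# species map for a locus_dataset (seq_id -> species)
species_map_of <- function(locus) {
  do.call(rbind, lapply(names(locus$species), function(s) {
    data.frame(seq_id = rownames(locus$species[[s]]), species = s,
               stringsAsFactors = FALSE)
  }))
}

#' McDonald-Kreitman table
#'
#' Descriptive counts of non-synonymous and synonymous polymorphisms (PN,
#' PS, within each ingroup species) and fixed differences (DN, DS, assigned
#' to a lineage by outgroup parsimony), with the MK odds ratio
#' (DN*PS)/(DS*PN).  This companion diagnostic uses parsimony for
#' ancestral/derived calls, unlike the probabilistic model; codons that are
#' both polymorphic and divergent contribute to both counts.  Sites whose
#' fixed difference cannot be polarised (outgroup matches neither species)
#' are skipped and counted in `unassigned`.
#'
#' @param locus a `locus_dataset` with exactly two ingroup species and one
#'   outgroup sequence.
#' @param outgroup name of the outgroup species in the dataset.
#' @param space a [codon_space()].
#' @return data.frame with one row per ingroup lineage: DN, DS, PN, PS and
#'   `odds_ratio` (`NA` where undefined); attribute `unassigned` counts
#'   unpolarised fixed differences.
#' @export
mk_table <- function(locus, outgroup, space = default_space()) {
  spp <- setdiff(names(locus$species), outgroup)
  if (length(spp) != 2L) stop("need exactly two ingroup species")
  if (!outgroup %in% names(locus$species))
    stop("no outgroup when lineage assignment requested")
  og <- locus$species[[outgroup]]
  if (nrow(og) != 1L) stop("outgroup must be a single sequence")
  aa <- space$aa_index
  out <- data.frame(lineage = spp, DN = 0L, DS = 0L, PN = 0L, PS = 0L)
  unassigned <- 0L
  major_of <- function(v) as.integer(names(which.max(table(v))))
  for (j in seq_len(locus$n_codons)) {
    al <- lapply(spp, function(s) locus$species[[s]][, j])
    # within-species polymorphism
    for (k in 1:2) {
      v <- al[[k]]
      if (length(unique(v)) > 1L) {
        mj <- major_of(v)
        for (minor in setdiff(unique(v), mj)) {
          if (aa[minor] != aa[mj]) out$PN[k] <- out$PN[k] + 1L
          else out$PS[k] <- out$PS[k] + 1L
        }
      }
    }
    # fixed difference between the species (disjoint allele sets)
    if (length(intersect(al[[1]], al[[2]])) == 0L) {
      m1 <- major_of(al[[1]]); m2 <- major_of(al[[2]])
      nonsyn <- aa[m1] != aa[m2]
      ogc <- og[1, j]
      lin <- if (ogc %in% al[[2]] || ogc == m2) 1L
      else if (ogc %in% al[[1]] || ogc == m1) 2L
      else NA_integer_
      if (is.na(lin)) unassigned <- unassigned + 1L
      else if (nonsyn) out$DN[lin] <- out$DN[lin] + 1L
      else out$DS[lin] <- out$DS[lin] + 1L
    }
  }
  out$odds_ratio <- ifelse(out$DS * out$PN > 0,
                           (out$DN * out$PS) / (out$DS * out$PN), NA_real_)
  attr(out, "unassigned") <- unassigned
  out
}
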