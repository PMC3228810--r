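#' The sense-codon state space
#'
#' Builds the state space of the multiallelic codon model: the K = 61 sense
#' codons of the standard genetic code (stop codons are treated as inviable
#' and removed from the space entirely), their amino-acid translation, and
#' the single-nucleotide neighbour graph annotated with transition versus
#' transversion status.
#'
#' Codons are ordered lexicographically with base order T, C, A, G (so the
#' first codon is TTT); this ordering is stable and shared by every matrix
#' and file the package produces.
#'
#' @param genetic_code_id Identifier of the genetic code. Only `"standard"`
#'   is supported.
#' @return An object of class `codon_space`: a list with elements
#'   \describe{
#'     \item{codons}{character vector of the 61 sense codons, fixed order}
#'     \item{amino_acid}{named character vector, codon to one-letter amino acid}
#'     \item{aa_index}{integer encoding of `amino_acid` (for fast comparison)}
#'     \item{neighbor}{61 x 61 0/1 matrix: codons differing at exactly one
#'       nucleotide position}
#'     \item{transition}{61 x 61 0/1 matrix: neighbouring codons whose
#'       differing position is a transition (A<->G or C<->T)}
#'   }
#' @examples
#' sp <- codon_space()
#' length(sp$codons)                       # 61
#' sum(sp$neighbor["ATG", ])               # 9 viable single-step neighbours
#' @export
codon_space <- function(genetic_code_id = "standard") {
  if (!identical(genetic_code_id, "standard"))
    stop("unknown genetic code id: ", genetic_code_id)
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  all64 <- paste0(grid$b1, grid$b2, grid$b3)
  aa64 <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", # TTT..TGG
    "LLLLPPPPHHQQRRRR", # CTT..CGG
    "IIIMTTTTNNKKSSRR", # ATT..AGG
    "VVVVAAAADDEEGGGG"  # GTT..GGG
  ), "")[[1]]
  names(aa64) <- all64
  codons <- all64[aa64 != "*"]
  aa <- aa64[codons]
  K <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  nb <- matrix(0L, K, K, dimnames = list(codons, codons))
  ts <- matrix(0L, K, K, dimnames = list(codons, codons))
  is_ts <- function(x, y) (x %in% c("A", "G") && y %in% c("A", "G")) ||
    (x %in% c("C", "T") && y %in% c("C", "T"))
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      d <- which(cmat[i, ] != cmat[j, ])
      if (length(d) == 1L) {
        nb[i, j] <- nb[j, i] <- 1L
        if (is_ts(cmat[i, d], cmat[j, d])) ts[i, j] <- ts[j, i] <- 1L
      }
    }
  }
  structure(list(codons = codons, amino_acid = aa,
                 aa_index = as.integer(factor(aa)),
                 neighbor = nb, transition = ts,
                 genetic_code_id = genetic_code_id),
            class = "codon_space")
}

#' @export
print.codon_space <- function(x, ...) {
  cat("Codon state space (", x$genetic_code_id, " code): ",
      length(x$codons), " sense codons, ",
      sum(x$neighbor) / 2L, " single-nucleotide neighbour pairs\n", sep = "")
  invisible(x)
}

# cached default space; the structure is a constant of the genetic code
the <- new.env(parent = emptyenv())

default_space <- function() {
  if (is.null(the$space)) the$space <- codon_space()
  the$space
}

#' Translate codon strings to state-space indices
#'
#' @param x character vector of codons (e.g. `"ATG"`).
#' @param space a [codon_space()].
#' @return integer indices into `space$codons`; `NA` for stop codons or
#'   codons containing ambiguity characters.
#' @export
codon_index <- function(x, space = default_space()) {
  match(toupper(x), space$codons)
}
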