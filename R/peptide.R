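## Peptide backbone layer: digestion, sequon registry, decoy proteins,
## b/y fragments and proton mobility.

.AA_RESIDUE_MASS <- local({
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1),
    A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2),
    P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1),
    T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1),
    I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2),
    D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),
    K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1),
    F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1),
    Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  vapply(comp, elemental_mass, numeric(1))
})

## Modification masses, Da.
.MOD_MASS <- c(
  carbamidomethyl = 57.0214637,   # C2H3NO on Cys, fixed
  oxidation = 15.9949146          # O on Met, variable
)

#' Find N-glycosylation sequons (N-X!=P-S/T) in a sequence
#' @param sequence amino-acid string.
#' @return integer positions (1-based) of the N.
#' @export
find_sequons <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 3L) return(integer(0))
  idx <- which(chars == "N")
  idx <- idx[idx <= n - 2L]
  idx[chars[idx + 1L] != "P" & chars[idx + 2L] %in% c("S", "T")]
}

#' Peptide mass with modifications
#'
#' @param sequence amino-acid string.
#' @param fixed_cys apply constant carbamidomethyl at every Cys.
#' @param var_mods data.frame(position, mass) of variable modifications.
#' @return monoisotopic neutral mass in Da.
#' @export
peptide_mass <- function(sequence, fixed_cys = TRUE, var_mods = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% names(.AA_RESIDUE_MASS)))
    stop("unknown residue in '", sequence, "'")
  m <- sum(.AA_RESIDUE_MASS[chars]) + WATER_MASS
  if (fixed_cys) m <- m + sum(chars == "C") * .MOD_MASS[["carbamidomethyl"]]
  if (!is.null(var_mods) && nrow(var_mods)) m <- m + sum(var_mods$mass)
  m
}

#' Digest a protein with a cleavage rule
#'
#' Trypsin by default: cleaves C-terminal to K/R, never before P. All peptides
#' with up to `max_missed` internal missed cleavages are returned with their
#' sequon registry; filtering to sequon-bearing peptides (the glycopeptide
#' search space) is the caller's choice via `sequon_only`.
#'
#' @param protein amino-acid string.
#' @param enzyme only `"trypsin"` built in; a custom rule may be supplied as a
#'   function(chars) returning cut positions (after-index).
#' @param max_missed maximum internal missed cleavage sites.
#' @param sequon_only keep only peptides containing at least one sequon.
#' @param min_length minimum peptide length.
#' @return data.frame(sequence, start, end, missed, sequons) where `sequons`
#'   is a comma-joined string of peptide-local N positions ("" if none).
#' @export
digest <- function(protein, enzyme = "trypsin", max_missed = 2L,
                   sequon_only = FALSE, min_length = 2L) {
  if (!nzchar(protein)) {
    return(data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed = integer(0),
                      sequons = character(0), stringsAsFactors = FALSE))
  }
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  cuts <- if (is.function(enzyme)) {
    enzyme(chars)
  } else if (identical(enzyme, "trypsin")) {
    which(chars %in% c("K", "R"))
  } else {
    stop("unknown enzyme: ", enzyme)
  }
  cuts <- cuts[cuts < n]
  if (!is.function(enzyme)) cuts <- cuts[chars[cuts + 1L] != "P"]
  bounds <- c(0L, cuts, n)                     # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  rows <- list()
  n_seg <- length(starts)
  for (i in seq_len(n_seg)) {
    for (j in i:min(n_seg, i + max_missed)) {
      s <- starts[i]; e <- ends[j]
      if (e - s + 1L < min_length) next
      seq_ <- substr(protein, s, e)
      sq <- find_sequons(seq_)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq_, start = s, end = e, missed = j - i,
        sequons = paste(sq, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), start = integer(0), end = integer(0),
               missed = integer(0), sequons = character(0),
               stringsAsFactors = FALSE)
  if (sequon_only) out <- out[nzchar(out$sequons), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse-decoy of a protein, preserving glycosite registry
#'
#' The whole sequence is reversed; every target sequon position is mapped to
#' its mirrored position and registered as a decoy glycosite even though the
#' local motif is disrupted. No new sequons enter the decoy registry.
#'
#' @param protein amino-acid string.
#' @param sites glycosite registry to mirror; defaults to the sequons found
#'   in `protein`. Pass a decoy's `decoy_sites` here to reverse a decoy
#'   (whose own motifs are disrupted) back to the original registry.
#' @return list(sequence, decoy_sites = integer positions in the decoy,
#'   target_sites = the original positions, is_decoy = TRUE).
#' @export
reverse_decoy <- function(protein, sites = find_sequons(protein)) {
  chars <- strsplit(protein, "")[[1]]
  revseq <- paste(rev(chars), collapse = "")
  list(sequence = revseq,
       decoy_sites = if (length(sites)) nchar(protein) - sites + 1L else integer(0),
       target_sites = sites,
       is_decoy = TRUE)
}

#' b/y backbone fragment masses of a peptide
#'
#' Neutral fragment masses: b_i is the sum of the first i residue masses
#' (plus modification deltas), y_i the last i residues plus water, so that
#' b_i + y_(n-i) equals the peptide mass. The `glycosylated` flag marks
#' fragments spanning an occupied glycosite (annotation only; fragments are
#' matched bare under stepped collision energy).
#'
#' @param sequence amino-acid string.
#' @param occupied peptide-local positions carrying a glycan.
#' @param fixed_cys apply carbamidomethyl at Cys.
#' @return data.frame(series, index, mass, glycosylated).
#' @export
backbone_fragments <- function(sequence, occupied = integer(0),
                               fixed_cys = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) {
    return(data.frame(series = character(0), index = integer(0),
                      mass = numeric(0), glycosylated = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- .AA_RESIDUE_MASS[chars]
  if (fixed_cys) res[chars == "C"] <- res[chars == "C"] +
      .MOD_MASS[["carbamidomethyl"]]
  cum <- cumsum(res)
  total <- cum[n]
  idx <- seq_len(n - 1L)
  b <- data.frame(series = "b", index = idx, mass = cum[idx],
                  glycosylated = vapply(idx, function(i) any(occupied <= i),
                                        logical(1)),
                  stringsAsFactors = FALSE)
  y <- data.frame(series = "y", index = idx,
                  mass = total - cum[n - idx] + WATER_MASS,
                  glycosylated = vapply(idx, function(i) any(occupied > n - i),
                                        logical(1)),
                  stringsAsFactors = FALSE)
  rbind(b, y)
}

#' Proton mobility class of a precursor
#'
#' Compares the count of basic residues (K, R, H) to the precursor charge:
#' more basic sites than protons pins every proton (immobile), equality gives
#' partial mobility, excess protons are mobile.
#'
#' @param sequence amino-acid string.
#' @param charge precursor charge (>= 1).
#' @return `"mobile"`, `"partial"` or `"immobile"`.
#' @export
proton_mobility <- function(sequence, charge) {
  stopifnot(charge >= 1)
  chars <- strsplit(sequence, "")[[1]]
  basic <- sum(chars %in% c("K", "R", "H"))
  if (basic > charge) "immobile" else if (basic == charge) "partial" else "mobile"
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write protein sequences to FASTA, optionally with reverse decoys
#' @param sequences named character vector.
#' @param path output file.
#' @param with_decoys append reversed sequences under `DECOY_` headers.
#' @export
write_fasta <- function(sequences, path, with_decoys = FALSE) {
  if (with_decoys) {
    dec <- vapply(sequences, function(s) reverse_decoy(s)$sequence,
                  character(1))
    names(dec) <- paste0("DECOY_", names(sequences))
    sequences <- c(sequences, dec)
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
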