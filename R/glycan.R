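## Glycan compositions: monosaccharide table, parsing, size/normalizer rules,
## peptide+Y ladder enumeration, decoy ladders and glycan coverage.

.MONOSACCHARIDES <- local({
  comp <- list(
    Hex    = c(C = 6, H = 10, O = 5),
    HexNAc = c(C = 8, H = 13, N = 1, O = 5),
    dHex   = c(C = 6, H = 10, O = 4),
    NeuAc  = c(C = 11, H = 17, N = 1, O = 8),
    NeuGc  = c(C = 11, H = 17, N = 1, O = 9),
    Pent   = c(C = 5, H = 8, O = 4)
  )
  data.frame(
    name = names(comp),
    residue_mass = vapply(comp, elemental_mass, numeric(1)),
    row.names = names(comp)
  )
})

## Residues whose glycosidic bonds survive collisional activation poorly:
## sialic acids are stripped before peptide+Y ladder formation.
.LABILE <- c("NeuAc", "NeuGc")

#' Monoisotopic residue mass of a monosaccharide
#'
#' Residue masses are the monomer minus water, computed from elemental
#' compositions (Hex C6H10O5, HexNAc C8H13NO5, dHex C6H10O4, NeuAc C11H17NO8,
#' NeuGc C11H17NO9, Pent C5H8O4).
#'
#' @param name monosaccharide symbol, e.g. `"HexNAc"`.
#' @return mass in Da.
#' @examples
#' residue_mass("HexNAc") # 203.0794
#' @export
residue_mass <- function(name) {
  if (!all(name %in% .MONOSACCHARIDES$name)) {
    stop("unknown monosaccharide: ",
         paste(setdiff(name, .MONOSACCHARIDES$name), collapse = ", "))
  }
  .MONOSACCHARIDES[name, "residue_mass"]
}

#' List of built-in monosaccharides
#' @return data.frame with columns `name`, `residue_mass`.
#' @export
monosaccharides <- function() .MONOSACCHARIDES[, c("name", "residue_mass")]

#' Construct a glycan composition
#'
#' @param counts named integer vector of residue counts (names from
#'   [monosaccharides()]); zeros are dropped.
#' @param glycan_type `"N"` or `"O"`.
#' @return a `glycan_composition`: list with `counts`, `cardinality`, `mass`,
#'   `glycan_type`.
#' @export
glycan_composition <- function(counts, glycan_type = "N") {
  counts <- counts[counts != 0]
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("counts must be named")
  if (any(counts < 0)) stop("negative monosaccharide count")
  bad <- setdiff(names(counts), .MONOSACCHARIDES$name)
  if (length(bad)) stop("unknown monosaccharide: ", paste(bad, collapse = ", "))
  counts <- counts[order(match(names(counts), .MONOSACCHARIDES$name))]
  storage.mode(counts) <- "integer"
  structure(
    list(
      counts = counts,
      cardinality = as.integer(sum(counts)),
      mass = if (length(counts)) sum(residue_mass(names(counts)) * counts) else 0,
      glycan_type = match.arg(glycan_type, c("N", "O"))
    ),
    class = "glycan_composition"
  )
}

count_of <- function(g, name) {
  v <- unname(g$counts[name])
  if (is.na(v)) 0L else v
}

#' @export
format.glycan_composition <- function(x, ...) {
  if (!length(x$counts)) return("{}")
  paste0("{", paste(sprintf("%s:%d", names(x$counts), x$counts),
                    collapse = "; "), "}")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan %s  mass %.4f  |g|=%d  type %s>\n",
              format(x), x$mass, x$cardinality, x$glycan_type))
  invisible(x)
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x)

#' Parse a glycan composition string
#'
#' Accepts the canonical `"{Hex:5; HexNAc:2}"` form and the concatenated
#' `"HexNAc(2)Hex(5)"` dialect.
#'
#' @param text composition string.
#' @param glycan_type `"N"` or `"O"`.
#' @return a [glycan_composition()].
#' @examples
#' parse_composition("{Hex:5; HexNAc:2}")
#' parse_composition("HexNAc(2)Hex(5)")
#' @export
parse_composition <- function(text, glycan_type = "N") {
  text <- trimws(text)
  if (grepl("^\\{", text)) {
    inner <- sub("^\\{", "", sub("\\}$", "", text))
    if (!nzchar(trimws(inner)))
      return(glycan_composition(integer(0), glycan_type))
    parts <- strsplit(inner, ";")[[1]]
    kv <- lapply(parts, function(p) {
      toks <- strsplit(trimws(p), ":")[[1]]
      if (length(toks) != 2L)
        stop("malformed composition token: '", trimws(p), "'")
      toks
    })
    nm <- vapply(kv, function(x) trimws(x[1]), character(1))
    ct <- suppressWarnings(as.integer(vapply(kv, function(x) trimws(x[2]),
                                             character(1))))
    if (anyNA(ct)) stop("non-integer count in composition: ", text)
  } else {
    m <- gregexpr("([A-Za-z]+)\\((-?[0-9]+)\\)", text)[[1]]
    if (m[1] == -1L) stop("unparseable composition: '", text, "'")
    toks <- regmatches(text, gregexpr("([A-Za-z]+)\\((-?[0-9]+)\\)", text))[[1]]
    if (sum(nchar(toks)) != nchar(gsub("\\s", "", text)))
      stop("unparseable composition: '", text, "'")
    nm <- sub("\\(.*$", "", toks)
    ct <- as.integer(sub("^.*\\((-?[0-9]+)\\)$", "\\1", toks))
  }
  if (any(ct < 0)) stop("negative count in composition: ", text)
  counts <- tapply(ct, nm, sum)
  glycan_composition(stats::setNames(as.integer(counts), names(counts)),
                     glycan_type)
}

#' Read a glycan composition list file
#'
#' One composition per line; `#` starts a comment; blank lines skipped.
#'
#' @param path file path.
#' @param glycan_type `"N"` or `"O"`.
#' @return list of [glycan_composition()] objects.
#' @export
read_glycan_list <- function(path, glycan_type = "N") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_composition, glycan_type = glycan_type)
}

#' Approximate glycan size n_g
#'
#' The residue count minus the labile sialic acids, deducting one when two or
#' more dHex are present (the second fucose rarely extends the fragment
#' ladder); floored at 0.
#'
#' @param g a [glycan_composition()].
#' @return integer size.
#' @export
approx_size <- function(g) {
  n <- g$cardinality - count_of(g, "NeuAc") - count_of(g, "NeuGc") -
    as.integer(count_of(g, "dHex") > 1L)
  max(n, 0L)
}

#' Fragment-count normalizer d_g for glycan coverage
#'
#' Approximates the number of distinct peptide+Y fragment masses a composition
#' of size `n_g` can yield: `n_g * log(n_g)` when core fucosylation is possible
#' (dHex present), half that otherwise, never below `n_g`. Natural log. For
#' `n_g < 2` returns `max(n_g, 1)` so coverage stays defined for one- and
#' two-residue O-glycan cores.
#'
#' @param g a [glycan_composition()], or an integer `n_g` when `dhex` given.
#' @param dhex override for the dHex count (used with integer `g`).
#' @return positive real normalizer.
#' @export
coverage_normalizer <- function(g, dhex = NULL) {
  if (inherits(g, "glycan_composition")) {
    n <- approx_size(g)
    d <- count_of(g, "dHex")
  } else {
    n <- as.numeric(g)
    d <- if (is.null(dhex)) 0 else dhex
  }
  if (n < 2) return(max(n, 1))
  raw <- if (d > 0) n * log(n) else 0.5 * n * log(n)
  max(raw, n)
}

## ---- peptide+Y ladder -----------------------------------------------------

## Rooted lower sets of the canonical HexNAc2Hex3 core tree, as
## (HexNAc, Hex) count pairs.  Branch-ambiguous subtrees collapse by mass so
## only the distinct compositions matter.
.CORE_SUBSETS <- matrix(
  c(0L, 0L,  1L, 0L,  2L, 0L,  2L, 1L,  2L, 2L,  2L, 3L),
  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("HexNAc", "Hex"))
)

comp_from_counts <- function(counts, glycan_type = "N") {
  glycan_composition(counts[counts > 0], glycan_type)
}

## All sub-multisets (as count matrices) of a named nonneg count vector.
sub_multisets <- function(counts) {
  if (!length(counts)) return(matrix(integer(0), nrow = 1, ncol = 0))
  grids <- lapply(counts, function(k) 0:k)
  g <- as.matrix(expand.grid(grids))
  colnames(g) <- names(counts)
  storage.mode(g) <- "integer"
  g
}

#' Generate the peptide+Y fragment ladder of a glycan composition
#'
#' For N-glycans covering the HexNAc2Hex3 core, the ladder is the set of
#' rooted sub-structures of the canonical core tree (flagged `is_core`), each
#' optionally decorated with one reducing-end dHex or Pent when those residues
#' are present, plus the full core extended by every sub-multiset of the
#' remaining non-labile residues. NeuAc/NeuGc are labile and never appended.
#' Compositions lacking the core (or O-glycans) fall back to combination-only
#' enumeration. Fragments with identical masses are merged; Y0 (bare peptide)
#' is always present.
#'
#' @param g a [glycan_composition()].
#' @return data.frame with columns `composition` (canonical string),
#'   `mass_delta` (Da above the bare peptide), `is_core`, `glycan_size`.
#' @export
generate_y_ladder <- function(g) {
  cnt <- function(nm) count_of(g, nm)
  has_core <- g$glycan_type == "N" && cnt("HexNAc") >= 2L && cnt("Hex") >= 3L
  rows <- list()
  add <- function(counts, core) {
    comp <- comp_from_counts(counts, g$glycan_type)
    rows[[length(rows) + 1L]] <<- data.frame(
      composition = format(comp), mass_delta = comp$mass,
      is_core = core, glycan_size = comp$cardinality,
      stringsAsFactors = FALSE)
  }
  if (has_core) {
    for (i in seq_len(nrow(.CORE_SUBSETS))) {
      base <- .CORE_SUBSETS[i, ]
      add(base, TRUE)
      if (sum(base) > 0L) {
        if (cnt("dHex") > 0L) add(c(base, dHex = 1L), TRUE)
        if (cnt("Pent") > 0L) add(c(base, Pent = 1L), TRUE)
      }
    }
    remaining <- g$counts
    core_used <- c(HexNAc = 2L, Hex = 3L)
    for (nm in names(core_used))
      remaining[nm] <- remaining[nm] - core_used[nm]
    remaining <- remaining[!(names(remaining) %in% .LABILE)]
    remaining <- remaining[remaining > 0]
    if (length(remaining)) {
      combos <- sub_multisets(remaining)
      for (i in seq_len(nrow(combos))) {
        extra <- combos[i, , drop = TRUE]
        if (sum(extra) == 0L) next
        counts <- c(HexNAc = 2L, Hex = 3L)
        for (nm in names(extra)) {
          counts[nm] <- ifelse(is.na(counts[nm]), 0L, counts[nm]) + extra[[nm]]
        }
        add(counts, FALSE)
      }
    }
  } else {
    nonlabile <- g$counts[!(names(g$counts) %in% .LABILE)]
    nonlabile <- nonlabile[nonlabile > 0]
    add(stats::setNames(integer(0), character(0)), TRUE)  # Y0
    if (length(nonlabile)) {
      combos <- sub_multisets(nonlabile)
      for (i in seq_len(nrow(combos))) {
        extra <- combos[i, , drop = TRUE]
        if (sum(extra) == 0L) next
        add(extra[extra > 0], FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  ## merge duplicate masses; a fragment reachable as core stays core
  key <- sprintf("%.5f", out$mass_delta)
  agg_core <- tapply(out$is_core, key, any)
  keep <- !duplicated(key)
  out <- out[keep, , drop = FALSE]
  out$is_core <- as.logical(agg_core[sprintf("%.5f", out$mass_delta)])
  out <- out[order(out$mass_delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a decoy peptide+Y ladder
#'
#' The target ladder with every fragment of glycan size >= 2 shifted by an
#' independent Uniform(1, 30) Da draw; Y0 and Y1 keep their exact target
#' masses so decoy matches retain the same trivial baseline as targets.
#' Reproducible from `seed`.
#'
#' @param g a [glycan_composition()].
#' @param seed integer seed for the shift draws.
#' @return the ladder data.frame with an extra `shift` column and
#'   `mass_delta` already shifted; attribute `seed` records the seed.
#' @export
make_decoy_ladder <- function(g, seed) {
  ladder <- generate_y_ladder(g)
  shifts <- numeric(nrow(ladder))
  n_shift <- sum(ladder$glycan_size >= 2L)
  if (n_shift > 0) {
    draws <- with_local_seed(seed, stats::runif(n_shift, 1.0, 30.0))
    shifts[ladder$glycan_size >= 2L] <- draws
  }
  ladder$shift <- shifts
  ladder$mass_delta <- ladder$mass_delta + shifts
  attr(ladder, "seed") <- seed
  ladder
}

#' Glycan coverage of a matched peptide+Y fragment set
#'
#' @param matched_masses mass deltas (Da above bare peptide) of the distinct
#'   ladder fragments matched in a spectrum.
#' @param g the [glycan_composition()] searched.
#' @param ladder optional precomputed ladder (target or decoy); regenerated
#'   from `g` when missing.
#' @param mass_tol absolute Da tolerance for identifying ladder entries.
#' @return list with `coverage_G` (distinct matches / d_g, clipped to `[0,1]`)
#'   and `coverage_G_core` (matched core fraction).
#' @export
glycan_coverage <- function(matched_masses, g, ladder = NULL,
                            mass_tol = 1e-4) {
  if (is.null(ladder)) ladder <- generate_y_ladder(g)
  if (nrow(ladder) == 0L) return(list(coverage_G = 0, coverage_G_core = 0))
  hit <- vapply(ladder$mass_delta, function(m) {
    any(abs(matched_masses - m) <= mass_tol)
  }, logical(1))
  d_g <- coverage_normalizer(g)
  cov_g <- min(sum(hit) / d_g, 1)
  n_core <- sum(ladder$is_core)
  cov_core <- if (n_core > 0) sum(hit & ladder$is_core) / n_core else 0
  list(coverage_G = cov_g, coverage_G_core = cov_core)
}
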