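# Module grammar for synthetic banded-fiber collagen chains.
#
# A design is a dash-separated string of module tokens read N -> C, e.g.
# "P10-B-P10" or "R5-B-E5". Adhesive tokens are P/R/E followed by an integer
# triplet count; any other alphanumeric token names a functional-driver
# fragment in the fragment library. All sequences follow the Xaa-Yaa-Gly
# triplet convention (Gly every third residue).

CHARGED_BASIC  <- c("K", "R")
CHARGED_ACIDIC <- c("D", "E")
AA_UNCHARGED_POOL <- c("A", "S", "T", "Q", "N") # X/Y positions of stand-in fragments

#' Construct a module specification
#'
#' Low-level constructor for one module of a designed collagen chain: a
#' hydrophobic (Pro-Pro-Gly) or electrostatic (Pro-Arg-Gly / Glu-Pro-Gly)
#' adhesive block, or a functional-driver fragment.
#'
#' Electrostatic adhesive modules are always 5 triplets (15 residues) long:
#' `n` charged triplets plus Pro-Pro-Gly padding. Padding is placed distal to
#' the functional driver so the charged block stays contiguous with the
#' overlap interface: for an N-terminal R module padding goes first, for a
#' C-terminal E module padding goes last.
#'
#' @param kind one of `"P"`, `"R"`, `"E"` (adhesives) or `"fragment"`.
#' @param n_triplets number of defining triplets (for R/E: number of charged
#'   triplets, at most 5).
#' @param triplets character vector of 3-residue triplets (required for
#'   fragments; derived for adhesives).
#' @param name module label used in annotations (defaults to the token form,
#'   e.g. `"P10"`).
#' @return an object of class `module_spec`.
#' @export
module_spec <- function(kind = c("P", "R", "E", "fragment"),
                        n_triplets = NULL, triplets = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "P") {
    stopifnot(is.numeric(n_triplets), n_triplets >= 1)
    triplets <- rep("PPG", n_triplets)
  } else if (kind %in% c("R", "E")) {
    stopifnot(is.numeric(n_triplets), n_triplets >= 1)
    if (n_triplets > 5) {
      stop("electrostatic adhesive modules hold at most 5 charged triplets (15 residues)")
    }
    pad <- rep("PPG", 5 - n_triplets)
    chg <- rep(if (kind == "R") "PRG" else "EPG", n_triplets)
    # padding distal to the driver: R modules are N-terminal (driver follows),
    # E modules are C-terminal (driver precedes)
    triplets <- if (kind == "R") c(pad, chg) else c(chg, pad)
  } else {
    if (is.null(triplets)) stop("fragment modules need explicit triplets")
    if (is.null(n_triplets)) n_triplets <- length(triplets)
    stopifnot(n_triplets == length(triplets))
  }
  bad <- triplets[nchar(triplets) != 3L | substr(triplets, 3, 3) != "G"]
  if (length(bad)) {
    stop("invalid triplet(s): ", paste(bad, collapse = ", "),
         " (every triplet must be 3 residues ending in G)")
  }
  if (is.null(name)) {
    name <- if (kind == "fragment") "frag" else paste0(kind, n_triplets)
  }
  structure(list(kind = kind, n_triplets = length(triplets),
                 triplets = triplets, name = name),
            class = "module_spec")
}

is_adhesive <- function(m) m$kind %in% c("P", "R", "E")

#' Residue sequence of one module
#'
#' @param m a `module_spec`.
#' @return the module's residue string.
#' @export
module_sequence <- function(m) paste(m$triplets, collapse = "")

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf("<module_spec> %s (%s), %d triplets: %s\n", x$name, x$kind,
              x$n_triplets, module_sequence(x)))
  invisible(x)
}

#' Generate a synthetic functional-driver fragment
#'
#' Generates Gly-every-third driver fragments standing in for the three
#' Scl2-derived fragment classes used in banded-fiber designs: class A is
#' chargeless, class B carries one copy of the integrin-binding GFPGER motif
#' (and otherwise at most two charged residues), and class C is charge-rich
#' (at least 30% of X/Y positions charged) with zero net charge.
#'
#' Under the Xaa-Yaa-Gly convention the GFPGER motif is realised as the
#' triplets FPG-ERG with the leading Gly supplied by the preceding triplet,
#' so class B fragments need at least 3 triplets.
#'
#' @param class fragment class, `"A"`, `"B"` or `"C"`.
#' @param n_triplets fragment length in triplets (default 27, i.e. 81 residues).
#' @param seed RNG seed; the fragment is deterministic given the seed.
#' @return a `module_spec` of kind `"fragment"` named after the class.
#' @export
make_fragment <- function(class = c("A", "B", "C"), n_triplets = 27L, seed = 1L) {
  class <- match.arg(class)
  n_triplets <- as.integer(n_triplets)
  if (n_triplets < 1L) stop("n_triplets must be positive")
  if (class == "B" && n_triplets < 3L) {
    stop("class B fragments need >= 3 triplets to carry the GFPGER motif")
  }
  with_seed(seed, {
    xs <- sample(AA_UNCHARGED_POOL, n_triplets, replace = TRUE)
    ys <- sample(AA_UNCHARGED_POOL, n_triplets, replace = TRUE)
    if (class == "B") {
      # FPG-ERG pair placed mid-fragment; preceding triplet's Gly completes GFPGER
      k <- max(2L, n_triplets %/% 2L)
      xs[k] <- "F"; ys[k] <- "P"
      xs[k + 1L] <- "E"; ys[k + 1L] <- "R"
    } else if (class == "C") {
      n_xy <- 2L * n_triplets
      n_chg <- 2L * max(1L, round(0.2 * n_xy)) # ~40% of X/Y positions, even
      pos <- sample(n_xy, n_chg)
      half <- n_chg %/% 2L
      res <- c(sample(CHARGED_BASIC, half, replace = TRUE),
               sample(CHARGED_ACIDIC, n_chg - half, replace = TRUE))
      xy <- c(xs, ys)
      xy[pos] <- res
      xs <- xy[seq_len(n_triplets)]
      ys <- xy[n_triplets + seq_len(n_triplets)]
    }
    module_spec("fragment", triplets = paste0(xs, ys, "G"), name = class)
  })
}

#' Build the default fragment library
#'
#' Named list of synthetic driver fragments available to
#' [parse_design()]: the 27-triplet classes `A`, `B`, `C` and a 13-triplet
#' half-length B fragment `Bh` (used for split-driver control topologies).
#'
#' @param seed master seed for fragment generation.
#' @param n_triplets length of the full fragments (default 27).
#' @return named list of `module_spec` fragments.
#' @export
fragment_library <- function(seed = 1L, n_triplets = 27L) {
  list(
    A  = make_fragment("A", n_triplets, seed = derive_seed(seed, "fragA")),
    B  = make_fragment("B", n_triplets, seed = derive_seed(seed, "fragB")),
    C  = make_fragment("C", n_triplets, seed = derive_seed(seed, "fragC")),
    Bh = {
      f <- make_fragment("B", max(3L, n_triplets %/% 2L),
                         seed = derive_seed(seed, "fragBh"))
      f$name <- "Bh"
      f
    }
  )
}

#' Parse a design grammar string into a collagen design
#'
#' Tokens are dash-separated and read N to C. `P<n>`, `R<n>`, `E<n>` denote
#' adhesive modules; any other alphanumeric token must name a fragment in
#' `fragments`.
#'
#' @param grammar design string, e.g. `"P10-B-P10"` or `"R5-B-E5"`.
#' @param fragments fragment library (see [fragment_library()]).
#' @param name design name (defaults to the grammar with dashes removed).
#' @return an object of class `collagen_design` with fields `name`, `modules`,
#'   `sequence` and per-residue `annotation`.
#' @export
parse_design <- function(grammar, fragments = fragment_library(),
                         name = gsub("-", "", grammar)) {
  tokens <- strsplit(grammar, "-", fixed = TRUE)[[1]]
  if (!length(tokens) || any(!nzchar(tokens))) {
    stop("malformed grammar: ", grammar)
  }
  modules <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (grepl("^[PRE][0-9]+$", tok)) {
      modules[[i]] <- module_spec(substr(tok, 1, 1),
                                  n_triplets = as.integer(substring(tok, 2)))
    } else if (grepl("^[A-Za-z][A-Za-z0-9]*$", tok)) {
      if (!tok %in% names(fragments)) stop("unknown fragment name: ", tok)
      modules[[i]] <- fragments[[tok]]
    } else {
      stop("malformed grammar token: ", tok)
    }
  }
  new_collagen_design(name, modules, grammar = grammar)
}

new_collagen_design <- function(name, modules, grammar = NULL) {
  seqs <- vapply(modules, module_sequence, character(1))
  labels <- vapply(seq_along(modules), function(i) {
    sprintf("m%d:%s", i, modules[[i]]$name)
  }, character(1))
  annotation <- rep(labels, times = nchar(seqs))
  design <- structure(
    list(name = name, grammar = grammar, modules = modules,
         sequence = paste(seqs, collapse = ""), annotation = annotation),
    class = "collagen_design")
  validate_design(design)
  design
}

validate_design <- function(design) {
  n <- sum(vapply(design$modules, function(m) 3L * m$n_triplets, integer(1)))
  stopifnot(nchar(design$sequence) == n, length(design$annotation) == n)
  chars <- seq_chars(design$sequence)
  # Gly at every position == 2 (mod 3) within each module's span
  offset <- 0L
  for (m in design$modules) {
    len <- 3L * m$n_triplets
    gly_pos <- offset + seq(3L, len, by = 3L)
    if (!all(chars[gly_pos] == "G")) {
      stop("Gly-every-third rule violated in module ", m$name)
    }
    offset <- offset + len
  }
  invisible(design)
}

#' Accessors for a collagen design's flanks and driver
#'
#' @param design a `collagen_design`.
#' @return `design_flanks()` returns a list with the first and last module;
#'   `driver_modules()` the list of interior fragment modules.
#' @export
design_flanks <- function(design) {
  m <- design$modules
  list(n_module = m[[1]], c_module = m[[length(m)]])
}

#' @rdname design_flanks
#' @export
driver_modules <- function(design) {
  Filter(function(m) m$kind == "fragment", design$modules)
}

#' @export
print.collagen_design <- function(x, ...) {
  cat(sprintf("<collagen_design> %s: %d modules, %d residues\n",
              x$name, length(x$modules), nchar(x$sequence)))
  cat("  modules:", paste(vapply(x$modules, `[[`, character(1), "name"),
                          collapse = " - "), "\n")
  invisible(x)
}

#' Classify a design as banding-competent or not
#'
#' A design can form banded fibers only if two adhesive modules flank the
#' functional driver(s). Hydrophobic (Pro-Pro-Gly) flanks promote assembly
#' once they reach 8 triplets; electrostatic Arg/Glu flanks once they carry
#' 5 charged triplets (their full 15-residue length).
#'
#' @param design a `collagen_design`.
#' @return a `competence_verdict`: list with logical `competent` and `reason`
#'   in `c("ok", "topology-missing-flank", "hydrophobic-below-threshold",
#'   "electrostatic-below-threshold")`.
#' @export
classify_banding <- function(design) {
  stopifnot(inherits(design, "collagen_design"))
  m <- design$modules
  n <- length(m)
  verdict <- function(ok, reason) {
    structure(list(competent = ok, reason = reason, design = design$name),
              class = "competence_verdict")
  }
  topology_ok <- n >= 3L && is_adhesive(m[[1]]) && is_adhesive(m[[n]]) &&
    all(vapply(m[seq(2L, n - 1L)], function(x) x$kind == "fragment", logical(1)))
  if (!topology_ok) return(verdict(FALSE, "topology-missing-flank"))
  kinds <- c(m[[1]]$kind, m[[n]]$kind)
  if (all(kinds == "P")) {
    nmin <- min(m[[1]]$n_triplets, m[[n]]$n_triplets)
    if (nmin >= 8L) verdict(TRUE, "ok") else verdict(FALSE, "hydrophobic-below-threshold")
  } else if (identical(kinds, c("R", "E"))) {
    n_charged <- function(mod) sum(mod$triplets %in% c("PRG", "EPG"))
    nmin <- min(n_charged(m[[1]]), n_charged(m[[n]]))
    if (nmin >= 5L) verdict(TRUE, "ok") else verdict(FALSE, "electrostatic-below-threshold")
  } else {
    # mixed or reversed flank types do not form a productive overlap interface
    verdict(FALSE, "topology-missing-flank")
  }
}

#' @export
print.competence_verdict <- function(x, ...) {
  cat(sprintf("<competence_verdict> %s: %s (%s)\n", x$design,
              if (x$competent) "banding-competent" else "not competent", x$reason))
  invisible(x)
}

#' Write designs to / read designs from FASTA
#'
#' FASTA headers carry the design name followed by the grammar, e.g.
#' `>P10BP10 modules=P10-B-P10`. Sequences are wrapped at 60 columns.
#'
#' @param designs a `collagen_design` or list of them.
#' @param file output path.
#' @return `write_fasta()` returns `file` invisibly; `read_fasta()` returns a
#'   named character vector of sequences with a `modules` attribute holding
#'   the grammar strings parsed from the headers.
#' @export
write_fasta <- function(designs, file) {
  if (inherits(designs, "collagen_design")) designs <- list(designs)
  seqs <- vapply(designs, `[[`, character(1), "sequence")
  hdr <- vapply(designs, function(d) {
    if (is.null(d$grammar)) d$name else paste0(d$name, " modules=", d$grammar)
  }, character(1))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, filepath = file, width = 60L)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  seqs <- as.character(aa)
  ok <- Biostrings::AA_STANDARD
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(seq_chars(seqs[i])), ok)
    if (length(bad)) {
      stop("non-standard amino-acid letter(s) in record ", i, ": ",
           paste(bad, collapse = ", "))
    }
  }
  full <- names(seqs)
  names(seqs) <- sub("\\s.*$", "", full)
  mods <- ifelse(grepl("modules=", full), sub("^.*modules=(\\S+).*$", "\\1", full), NA)
  attr(seqs, "modules") <- mods
  seqs
}
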