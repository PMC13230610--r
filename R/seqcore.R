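#' DNA sequence constructor
#'
#' Canonicalizes a DNA sequence: whitespace stripped, upper-cased, strict
#' ACGT alphabet. Enumerated oligo design requires exact sequences, so IUPAC
#' ambiguity codes are rejected rather than expanded.
#'
#' @param x Character scalar (case-insensitive, may contain whitespace).
#' @return A character scalar of class `dna` over the alphabet ACGT.
#' @examples
#' dna("ggt tac GCC")
#' @export
dna <- function(x) {
  if (length(x) != 1L || !is.character(x) || is.na(x)) {
    stop("`x` must be a single non-NA character string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]", "", x))
  if (nchar(s) > 0L && grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop("non-ACGT character(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(s, class = "dna")
}

#' @export
print.dna <- function(x, ...) {
  cat(sprintf("<dna, %d nt> %s\n", nchar(x), unclass(x)))
  invisible(x)
}

as_dna <- function(x) if (inherits(x, "dna")) x else dna(x)

#' Reverse complement
#'
#' Watson-Crick reverse complement; an involution.
#'
#' @param s A [dna()] sequence (or string coercible to one).
#' @return A `dna` sequence.
#' @examples
#' revcomp(dna("ggttacgccgaacatgatc"))
#' @export
revcomp <- function(s) {
  s <- as_dna(s)
  if (nchar(s) == 0L) return(dna(""))
  dna(as.character(Biostrings::reverseComplement(Biostrings::DNAString(unclass(s)))))
}

#' Translate a DNA sequence
#'
#' Standard genetic code; stop codons become `*`; a trailing partial codon
#' is dropped.
#'
#' @param s A [dna()] sequence.
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return Single-letter amino-acid string.
#' @examples
#' translate_dna(dna("AACTAT"))
#' @export
translate_dna <- function(s, frame = 0L) {
  s <- as_dna(s)
  stopifnot(frame %in% 0:2)
  n <- nchar(s) - frame
  if (n < 3L) stop("sequence too short to translate in frame ", frame, call. = FALSE)
  sub <- substr(unclass(s), frame + 1L, frame + 3L * (n %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE))
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# all 64 codons -> amino acid under the standard code (stop = "*")
codon_map <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  aa <- vapply(codons, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)), "")
  stats::setNames(aa, codons)
}

#' Codon choice table
#'
#' A one-codon-per-amino-acid table used to encode enumerated substitution
#' payloads. Every codon must translate to its key; exactly the 20 standard
#' amino acids must be present.
#'
#' @param codons Named character vector: names are single-letter amino-acid
#'   codes, values are 3-nt codons.
#' @param name Identifier stored with the table.
#' @return A `codon_choice_table`.
#' @seealso [midas_codon_table()] for the default table.
#' @export
codon_choice_table <- function(codons, name = "custom") {
  codons <- toupper(codons)
  if (!setequal(names(codons), AA20) || length(codons) != 20L) {
    stop("table must map exactly the 20 standard amino acids", call. = FALSE)
  }
  if (any(nchar(codons) != 3L)) stop("codons must be 3 nt", call. = FALSE)
  cm <- codon_map()
  ok <- cm[codons] == names(codons)
  if (!all(ok)) {
    stop("codon(s) do not translate to their key: ",
         paste(codons[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(codons = codons[order(names(codons))], name = name),
            class = "codon_choice_table")
}

#' Default codon choice table
#'
#' The mammalian-expression codon set used throughout the packaged primer
#' fixtures (one high-usage human codon per amino acid, e.g. Ala = GCC,
#' Ser = TCC, Arg = AGA).
#'
#' @return A [codon_choice_table()] named `"midas-paper"`.
#' @export
midas_codon_table <- function() {
  codon_choice_table(c(
    A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
    G = "GGG", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
    M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "AGA",
    S = "TCC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC"
  ), name = "midas-paper")
}

#' @export
print.codon_choice_table <- function(x, ...) {
  cat(sprintf("<codon_choice_table '%s'>\n", x$name))
  print(x$codons)
  invisible(x)
}

#' Melting-temperature parameters
#'
#' Conditions for the nearest-neighbor duplex Tm calculation.
#'
#' @param method Currently only `"nn-santalucia1998"` (unified NN parameter
#'   set with the 0.368 * N * ln\[Na+\] entropic salt correction).
#' @param na_mM Monovalent cation concentration, mM.
#' @param oligo_nM Total single-strand concentration, nM (CT/4 is used for
#'   non-self-complementary duplexes).
#' @return A `tm_params` list.
#' @export
tm_params <- function(method = "nn-santalucia1998", na_mM = 50, oligo_nM = 500) {
  method <- match.arg(method)
  if (na_mM <= 0 || oligo_nM <= 0) stop("concentrations must be > 0", call. = FALSE)
  structure(list(method = method, na_mM = na_mM, oligo_nM = oligo_nM),
            class = "tm_params")
}

# Unified NN parameters (kcal/mol; cal/mol/K), 5'->3' top-strand dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor duplex melting temperature
#'
#' Two-state NN Tm for a perfect duplex of `s` with its complement, using the
#' unified parameter set (terminal A/T and G/C initiation terms, symmetry
#' correction for self-complementary oligos) and an entropic monovalent-salt
#' correction. Deterministic; used for the 60-66 degC primer-overlap window.
#'
#' @param s A [dna()] sequence, 6-60 nt.
#' @param params A [tm_params()].
#' @return Tm in degrees Celsius.
#' @examples
#' melting_temperature(dna("ACGTACGTACGTACGTACGT"))
#' @export
melting_temperature <- function(s, params = tm_params()) {
  s <- as_dna(s)
  n <- nchar(s)
  if (n < 6L || n > 60L) {
    stop("Tm defined for 6-60 nt oligos, got ", n, " nt", call. = FALSE)
  }
  ch <- strsplit(unclass(s), "")[[1]]
  steps <- paste0(ch[-n], ch[-1])
  dh <- sum(NN_DH[steps])            # kcal/mol
  ds <- sum(NN_DS[steps])            # cal/mol/K
  # initiation terms per terminal pair
  for (term in ch[c(1L, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                       { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  selfcomp <- identical(unclass(revcomp(s)), unclass(s))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(params$na_mM / 1000)
  ct <- params$oligo_nM * 1e-9
  x <- if (selfcomp) 1 else 4
  dh * 1000 / (ds + 1.9872 * log(ct / x)) - 273.15
}

#' Minimum codon changes to reach an amino acid
#'
#' Minimum Hamming distance from a codon to any codon of a target amino
#' acid, with all distance-achieving codons and their changed-base patterns.
#' Useful for judging which substitutions are reachable by random
#' single-base mutagenesis and which require multi-base changes.
#'
#' @param from_codon 3-nt [dna()] codon.
#' @param to_aa Single-letter amino-acid code (or `"*"` for stop).
#' @return List with `min_changes` (integer), and `paths`: a data.frame of
#'   the minimal target codons, the changed positions, and the `from -> to`
#'   base pattern at those positions.
#' @examples
#' min_codon_changes(dna("GAC"), "S")   # Asp -> Ser needs a double change
#' @export
min_codon_changes <- function(from_codon, to_aa) {
  from_codon <- as_dna(from_codon)
  if (nchar(from_codon) != 3L) stop("`from_codon` must be 3 nt", call. = FALSE)
  to_aa <- toupper(to_aa)
  cm <- codon_map()
  if (!to_aa %in% cm) stop("invalid amino-acid code: ", to_aa, call. = FALSE)
  targets <- names(cm)[cm == to_aa]
  fb <- strsplit(unclass(from_codon), "")[[1]]
  dist <- vapply(targets, function(cd) {
    sum(strsplit(cd, "")[[1]] != fb)
  }, integer(1))
  m <- min(dist)
  hit <- targets[dist == m]
  paths <- do.call(rbind, lapply(hit, function(cd) {
    tb <- strsplit(cd, "")[[1]]
    pos <- which(tb != fb)
    data.frame(
      codon = cd,
      positions = paste(pos, collapse = ","),
      pattern = if (length(pos)) {
        paste0(paste(fb[pos], collapse = ""), "->", paste(tb[pos], collapse = ""))
      } else "",
      stringsAsFactors = FALSE
    )
  }))
  list(min_changes = m, paths = paths)
}
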