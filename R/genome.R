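# Binary genome encoding of model-building decisions and the GA string
# operators.

#' Define a model decision slot
#'
#' A slot maps a fixed-width bit field to one of an ordered list of
#' decision outcomes.  The field width is `ceiling(log2(n_options))`
#' (0 bits for a single-option slot) and a bit pattern decodes to option
#' `value %% n_options + 1`, so every pattern is valid; the modulus rule
#' slightly overweights early options when the option count is not a power
#' of two.
#'
#' @param name slot label.
#' @param options list of decision outcomes.  For the standard assembly
#'   rule each option is `NULL` (no change) or a named list of patches:
#'   `effect` (a [covariate_effect()] to append), `iiv` (named iiv kinds to
#'   set), `residual` (residual kind), `structural` (structural kind) or
#'   `init` (list merged into the spec's initial values).
#' @return An object of class `decision_slot`.
#' @export
decision_slot <- function(name, options) {
  n <- length(options)
  if (n < 1) stop("a slot needs at least one option")
  structure(list(name = name, options = options,
                 width = if (n == 1) 0L else as.integer(ceiling(log2(n)))),
            class = "decision_slot")
}

#' Define a model search space
#'
#' @param slots list of [decision_slot()]s; slot order is the genome's bit
#'   order and the order in which covariate effects are applied.
#' @param base a [model_spec()] which the slot patches modify.
#' @param assemble optional custom function `(choices, base) -> model_spec`
#'   where `choices` is the list of selected options; defaults to the patch
#'   interpretation documented in [decision_slot()].
#' @return An object of class `search_space` with `total_bits`.
#' @export
search_space <- function(slots, base, assemble = NULL) {
  widths <- vapply(slots, `[[`, integer(1), "width")
  structure(list(slots = slots, base = base,
                 assemble = if (is.null(assemble)) assemble_patches
                            else assemble,
                 widths = widths, total_bits = sum(widths)),
            class = "search_space")
}

assemble_patches <- function(choices, base) {
  spec <- base
  effects <- base$effects
  iiv <- base$iiv
  residual <- base$residual
  structural <- base$structural
  init <- base$init
  for (ch in choices) {
    if (is.null(ch)) next
    if (!is.null(ch$effect)) effects <- c(effects, list(ch$effect))
    if (!is.null(ch$iiv)) iiv[names(ch$iiv)] <- ch$iiv
    if (!is.null(ch$residual)) residual <- ch$residual
    if (!is.null(ch$structural)) structural <- ch$structural
    if (!is.null(ch$init)) init[names(ch$init)] <- ch$init
  }
  # a residual-kind patch may change the number of error variances
  n_sig <- if (residual == "combined") 2L else 1L
  if (!is.null(init$sigma) && length(init$sigma) != n_sig)
    init$sigma <- rep_len(init$sigma, n_sig)
  model_spec(structural, effects = effects,
             iiv = iiv[names(iiv) %in% structural_parameters(structural)],
             residual = residual, init = init,
             theta_bounds = base$theta_bounds)
}

bits_to_int <- function(bits) {
  # first bit is the most significant
  v <- 0
  for (b in bits) v <- v * 2 + b
  v
}

genome_bits <- function(g) as.integer(strsplit(g, "")[[1]])

#' Decode a genome into a model specification
#'
#' @param g genome: a string of 0/1 characters of length
#'   `space$total_bits`.
#' @param space a [search_space()].
#' @return The assembled [model_spec()]; decoding is deterministic and
#'   total (every bit pattern is valid).
#' @export
decode <- function(g, space) {
  ch <- decode_choices(g, space)
  space$assemble(lapply(seq_along(space$slots),
                        function(i) space$slots[[i]]$options[[ch[i]]]),
                 space$base)
}

#' Decode a genome into per-slot option indices
#'
#' @inheritParams decode
#' @return Integer vector of 1-based option indices, one per slot.
#' @export
decode_choices <- function(g, space) {
  bits <- genome_bits(g)
  if (length(bits) != space$total_bits)
    stop("genome length ", length(bits), " != ", space$total_bits)
  pos <- 0L
  vapply(space$slots, function(sl) {
    n <- length(sl$options)
    if (sl$width == 0L) return(1L)
    v <- bits_to_int(bits[pos + seq_len(sl$width)])
    pos <<- pos + sl$width
    as.integer(v %% n) + 1L
  }, integer(1))
}

#' Encode per-slot option indices as the canonical genome
#'
#' The canonical code of option `i` is the smallest bit pattern decoding
#' to it, i.e. the binary representation of `i - 1`.
#'
#' @param choices integer vector of 1-based option indices per slot.
#' @param space a [search_space()].
#' @return Genome string; `decode_choices(encode(c), space)` reproduces
#'   `c`.
#' @export
encode <- function(choices, space) {
  if (length(choices) != length(space$slots))
    stop("one choice per slot required")
  bits <- unlist(lapply(seq_along(space$slots), function(i) {
    sl <- space$slots[[i]]
    idx <- choices[i]
    if (idx < 1 || idx > length(sl$options))
      stop("choice ", idx, " out of range for slot ", sl$name)
    if (sl$width == 0L) return(integer(0))
    v <- idx - 1L
    out <- integer(sl$width)
    for (b in sl$width:1) { out[b] <- v %% 2L; v <- v %/% 2L }
    out
  }))
  paste(bits, collapse = "")
}

#' Single-point crossover of two genomes
#'
#' Draws a cut point `N` uniformly on `{1, ..., L-1}` and swaps the first
#' `N` bits: offspring 1 takes the prefix of `p2` and suffix of `p1`,
#' offspring 2 the reverse.
#'
#' @param p1,p2 genome strings of equal length `L >= 2`.
#' @param n optional fixed cut point (used in tests); random by default.
#' @return List of the two offspring genome strings.
#' @export
crossover <- function(p1, p2, n = NULL) {
  L <- nchar(p1)
  if (nchar(p2) != L) stop("genome length mismatch")
  if (L < 2) stop("crossover needs L >= 2")
  if (is.null(n)) n <- sample.int(L - 1L, 1L)
  list(paste0(substr(p2, 1, n), substr(p1, n + 1, L)),
       paste0(substr(p1, 1, n), substr(p2, n + 1, L)))
}

#' Per-bit mutation of a genome
#'
#' @param g genome string.
#' @param rate probability of flipping each bit independently.
#' @return Mutated genome string.
#' @export
mutate <- function(g, rate = 0.01) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  bits <- genome_bits(g)
  flip <- runif(length(bits)) < rate
  bits[flip] <- 1L - bits[flip]
  paste(bits, collapse = "")
}

#' Hamming distance between two genomes
#'
#' @param g1,g2 genome strings of equal length.
#' @return Number of differing bit positions.
#' @export
hamming <- function(g1, g2) {
  if (nchar(g1) != nchar(g2)) stop("genome length mismatch")
  sum(genome_bits(g1) != genome_bits(g2))
}

#' All one-bit neighbors of a genome
#'
#' @param g genome string of length `L`.
#' @return Character vector of `L` genomes, the i-th differing from `g`
#'   only at bit i.
#' @export
one_bit_neighbors <- function(g) {
  bits <- genome_bits(g)
  vapply(seq_along(bits), function(i) {
    b <- bits; b[i] <- 1L - b[i]
    paste(b, collapse = "")
  }, character(1))
}

#' Covariate-selection search space
#'
#' Builds the standard search space for a covariate-identification
#' experiment: one two-option slot (`absent`/`present`) per candidate
#' covariate effect, with the structural model, IIV and residual
#' structures fixed at the base model.
#'
#' @param base a [model_spec()] (typically covariate-free).
#' @param candidates list of [covariate_effect()]s, one slot each; slot
#'   order fixes the genome layout and the effect application order.
#' @return A [search_space()] with `total_bits = length(candidates)`.
#' @export
covariate_search_space <- function(base, candidates) {
  slots <- lapply(candidates, function(e)
    decision_slot(effect_label(e), list(NULL, list(effect = e))))
  search_space(slots, base)
}
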