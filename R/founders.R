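#' Simulate a structured founder panel
#'
#' Draws haploid founder genotypes from a two-level hierarchical allele
#' frequency model: each marker has an ancestral frequency shared by all
#' populations, and each population draws its own frequency around it with
#' differentiation `Fst` (Balding-Nichols Beta sampling).  Founders are
#' assigned to populations as evenly as possible and carry alternating
#' mating types; MATalpha founders carry the `arg8::URA3` auxotrophy marker
#' used for diploid selection during intercrossing.
#'
#' @param n_founders Number of founder haplotypes (>= 2; default 25).
#' @param n_populations Number of ancestral populations (default 5).
#' @param map A [genetic_map()].
#' @param Fst Differentiation parameter in `[0, 1)`.  `Fst = 0` makes all
#'   populations share the ancestral frequency exactly.
#' @param seed Optional integer seed.
#' @param p_range Range of the ancestral allele frequency draw (uniform).
#' @return An object of class `founder_panel` with elements `founders`
#'   (data.frame: founder_id, population, mating_type, aux_arg8),
#'   `haplotypes` (founders x markers 0/1 matrix), `pop_freqs`
#'   (populations x markers), `ancestral_freq`, `Fst` and `map`.
#' @export
simulate_founders <- function(n_founders = 25, n_populations = 5, map,
                              Fst = 0.2, seed = NULL,
                              p_range = c(0.1, 0.9)) {
  if (n_founders < 2) stop("design error: need at least 2 founders")
  if (n_populations < 1 || n_populations > n_founders)
    stop("n_populations must be in [1, n_founders]")
  if (Fst < 0 || Fst >= 1) stop("parameter error: Fst must be in [0, 1)")
  stopifnot(inherits(map, "genetic_map"))
  if (!is.null(seed)) set.seed(seed)

  m <- nrow(map$markers)
  p_anc <- stats::runif(m, p_range[1], p_range[2])
  if (Fst > 0) {
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    pop_freqs <- t(vapply(seq_len(n_populations),
                          function(k) stats::rbeta(m, a, b), numeric(m)))
  } else {
    pop_freqs <- matrix(rep(p_anc, each = n_populations), n_populations, m)
  }
  pop <- sort(rep_len(seq_len(n_populations), n_founders))
  hap <- t(vapply(seq_len(n_founders), function(i) {
    stats::rbinom(m, 1L, pop_freqs[pop[i], ])
  }, integer(m)))
  ids <- sprintf("F%02d", seq_len(n_founders))
  dimnames(hap) <- list(ids, map$markers$id)
  mt <- rep_len(c("MATa", "MATalpha"), n_founders)
  founders <- data.frame(
    founder_id = ids,
    population = sprintf("P%d", pop),
    mating_type = mt,
    aux_arg8 = as.integer(mt == "MATalpha"),
    stringsAsFactors = FALSE)
  structure(list(founders = founders, haplotypes = hap,
                 pop_freqs = pop_freqs, ancestral_freq = p_anc,
                 Fst = Fst, map = map),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", nrow(x$founders), "founders,",
      length(unique(x$founders$population)), "populations, Fst =", x$Fst,
      "\n")
  invisible(x)
}
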