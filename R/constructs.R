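#' Define a biosensor construct
#'
#' A named GPER linker fragment (1-based inclusive residue range) inserted
#' between the donor and acceptor fluorescent proteins, optionally flanked
#' by glycine spacers.
#'
#' @param linker_start,linker_end Residue indices of the linker (1-based,
#'   inclusive, receptor numbering); `linker_start <= linker_end`.
#' @param smd Submembrane domain the fragment belongs to (1–4).
#' @param n_flank_gly,c_flank_gly Number of glycine residues added at the
#'   N-/C-terminal ends of the linker (>= 0).
#' @param name Construct name; derived from the range and flanks when
#'   omitted (e.g. `"BSGPER_GGG83-93GGG"`).
#' @return A list of class `biosensor_construct`.
#' @export
biosensor_construct <- function(linker_start, linker_end, smd = NA_integer_,
                                n_flank_gly = 0L, c_flank_gly = 0L,
                                name = NULL) {
  if (linker_start > linker_end)
    fb_stop("linker_start must be <= linker_end", "fretbind_range_error")
  if (n_flank_gly < 0 || c_flank_gly < 0)
    fb_stop("flank counts must be >= 0", "fretbind_parameter_error")
  if (is.null(name))
    name <- paste0("BSGPER_", strrep("G", n_flank_gly), linker_start, "-",
                   linker_end, strrep("G", c_flank_gly))
  structure(list(name = name, linker_start = linker_start,
                 linker_end = linker_end, smd = smd,
                 n_flank_gly = n_flank_gly, c_flank_gly = c_flank_gly),
            class = "biosensor_construct")
}

#' @export
print.biosensor_construct <- function(x, ...) {
  cat(sprintf("<biosensor_construct> %s (SMD%s, a.a. %d-%d)\n", x$name,
              x$smd, x$linker_start, x$linker_end))
  invisible(x)
}

#' Enumerate truncation/flank variants of a base construct
#'
#' Generates the family of biosensors used to narrow down a binding domain:
#' every combination of C-terminal truncation end and glycine flank count,
#' uniquely named by range and flanks.
#'
#' @param base A [biosensor_construct()] defining the full fragment.
#' @param truncation_ends Integer vector of alternative `linker_end` values
#'   (must lie within the base range). Empty means keep the base end.
#' @param gly_flank_options Integer vector of symmetric glycine flank
#'   counts to combine with each end (default 0).
#' @return A list of `biosensor_construct` objects.
#' @export
#' @examples
#' smd4 <- biosensor_construct(330, 375, smd = 4)
#' vapply(enumerate_constructs(smd4, c(345, 351, 361, 375)),
#'        `[[`, character(1), "name")
enumerate_constructs <- function(base, truncation_ends = integer(),
                                 gly_flank_options = 0L) {
  stopifnot(inherits(base, "biosensor_construct"))
  if (length(truncation_ends) == 0L && identical(gly_flank_options, 0L))
    return(list(base))
  if (length(truncation_ends) == 0L)
    truncation_ends <- base$linker_end
  if (any(truncation_ends < base$linker_start |
          truncation_ends > base$linker_end))
    fb_stop("truncation ends must lie within the base linker range",
            "fretbind_range_error")
  out <- list()
  for (end in truncation_ends) {
    for (g in gly_flank_options) {
      out[[length(out) + 1L]] <- biosensor_construct(
        base$linker_start, end, smd = base$smd,
        n_flank_gly = g, c_flank_gly = g)
    }
  }
  out
}

#' Published calmodulin-binding parameters of the GPER biosensors
#'
#' Reference characterization of the GPER submembrane-domain biosensors:
#' dynamic range and apparent K_d for calmodulin of each construct. These
#' values parameterize the synthetic generator when emulating each
#' construct's titration.
#'
#' @return Data frame with columns `construct`, `smd`, `dynamic_range`,
#'   `kd_um`.
#' @export
gper_binding_params <- function() {
  data.frame(
    construct = c("BSGPER_83-93", "BSGPER_150-175", "BSGPER_150-170",
                  "BSGPER_242-259", "BSGPER_330-351", "BSGPER_330-345"),
    smd = c(1L, 2L, 2L, 3L, 4L, 4L),
    dynamic_range = c(1.31, 1.61, 1.34, 2.65, 2.50, 2.45),
    kd_um = c(136.62, 0.44, 3.41, 8.01, 1.40, 1.60)
  )
}

#' Published Ca2+ sensitivities of the GPER-calmodulin complexes
#'
#' Reference EC50(Ca2+) and Hill coefficients for the complexes between
#' calmodulin and the GPER submembrane-domain fragments; the SMD1 complex
#' forms two species with distinct Ca2+ sensitivities.
#'
#' @return Data frame with columns `complex`, `smd`, `species`, `ec50_um`,
#'   `hill_n`.
#' @export
gper_ca_params <- function() {
  data.frame(
    complex = c("CaM-GPER_83-93 sp1", "CaM-GPER_83-93 sp2",
                "CaM-GPER_150-175", "CaM-GPER_242-259", "CaM-GPER_330-351"),
    smd = c(1L, 1L, 2L, 3L, 4L),
    species = c(1L, 2L, NA, NA, NA),
    ec50_um = c(0.13, 3.71, 2.38, 5.15, 0.75),
    hill_n = c(1.99, 2.53, 1.21, 1.43, 1.18)
  )
}
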