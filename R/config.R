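# YAML configuration I/O.  Keys mirror the fitness-table symbols:
# s_AA_f, s_Aa_f, s_aa_f, s_AA_m, s_Aa_m, s_aa_m, sigma, d, H.

#' Read a fitness scheme from a YAML configuration file
#'
#' @param path Path to a YAML file (or a list already parsed from one) with
#'   keys `s_AA_f`, `s_Aa_f`, `s_aa_f` (female-role coefficients), optional
#'   `s_AA_m`, `s_Aa_m`, `s_aa_m` (male role, defaulting to the female
#'   values), and `sigma`, `d`, `H`.
#' @return A [fitness_scheme()].
#' @export
read_fitness_scheme <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  need <- c("s_AA_f", "s_Aa_f", "s_aa_f")
  if (!all(need %in% names(cfg))) {
    stop("config must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  sf <- c(AA = cfg$s_AA_f, Aa = cfg$s_Aa_f, aa = cfg$s_aa_f)
  sm <- c(AA = cfg$s_AA_m %||% cfg$s_AA_f,
          Aa = cfg$s_Aa_m %||% cfg$s_Aa_f,
          aa = cfg$s_aa_m %||% cfg$s_aa_f)
  fitness_scheme(sf, sm,
                 sigma = cfg$sigma %||% 0,
                 d = cfg$d %||% 0,
                 H = cfg$H %||% 2)
}

#' Write a fitness scheme to a YAML configuration file
#'
#' @param scheme A [fitness_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fitness_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "fitness_scheme"))
  yaml::write_yaml(list(
    s_AA_f = unname(scheme$s_female[["AA"]]),
    s_Aa_f = unname(scheme$s_female[["Aa"]]),
    s_aa_f = unname(scheme$s_female[["aa"]]),
    s_AA_m = unname(scheme$s_male[["AA"]]),
    s_Aa_m = unname(scheme$s_male[["Aa"]]),
    s_aa_m = unname(scheme$s_male[["aa"]]),
    sigma = scheme$sigma, d = scheme$d, H = scheme$H
  ), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
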