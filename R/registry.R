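#' The survival registry
#'
#' The registry maps every stratum the simulation needs to a parametric
#' survival distribution. Strata (all time scales in days):
#'
#' * posttransplant survival per diagnosis: `HCC`, `PBC`, `PSC`, `ALF`, `AC`,
#'   `Others`, plus the CRLM trial arms `SECA1` and `SECA2` (all carry
#'   `cap_years = 10`, the switch to background mortality);
#' * `palliative`: overall survival under palliative chemotherapy;
#' * waiting-list competing risks per diagnosis: `wl_death:<diag>` and
#'   `wl_dropout:<diag>` for `<diag>` in HCC, PBC, PSC, ALF, AC, Others, CRLM.
#'
#' A registry is a tibble with columns `stratum`, `family`, `par1`, `par2`,
#' `cap_years`. `par1`/`par2` follow the parameter order of [surv_dist()]
#' (exponential: scale, `par2 = NA`; weibull/log-logistic: shape, scale;
#' lognormal: meanlog, sdlog; gompertz: rate, shape).
#'
#' @name survival_registry
NULL

sq_diagnoses <- function() c("HCC", "PBC", "PSC", "ALF", "AC", "Others")

treatment_strata <- function() {
  c(sq_diagnoses(), "palliative", "SECA1", "SECA2")
}

wl_strata <- function() {
  diag <- c(sq_diagnoses(), "CRLM")
  c(paste0("wl_death:", diag), paste0("wl_dropout:", diag))
}

registry_row <- function(stratum, dist) {
  p <- dist$params
  tibble::tibble(stratum = stratum, family = dist$family,
                 par1 = unname(p[1]), par2 = if (length(p) > 1) unname(p[2]) else NA_real_,
                 cap_years = if (is.null(dist$cap_years)) NA_real_ else dist$cap_years)
}

#' Look up a stratum as a distribution
#'
#' @param registry A registry tibble, see [survival_registry].
#' @param stratum Stratum name.
#' @return A [surv_dist()].
#' @export
registry_dist <- function(registry, stratum) {
  i <- which(registry$stratum == stratum)
  if (length(i) != 1L) {
    stop("registry is missing stratum '", stratum, "'", call. = FALSE)
  }
  fam <- registry$family[i]
  nms <- surv_param_names(fam)
  pars <- stats::setNames(c(registry$par1[i], registry$par2[i])[seq_along(nms)], nms)
  cap <- registry$cap_years[i]
  do.call(surv_dist, c(list(fam), as.list(pars),
                       list(cap_years = if (is.na(cap)) NULL else cap)))
}

validate_registry <- function(registry) {
  need <- c(treatment_strata(), wl_strata())
  missing <- setdiff(need, registry$stratum)
  if (length(missing)) {
    stop("registry is missing strata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (s in need) registry_dist(registry, s) # parameter validity
  invisible(registry)
}

#' Read or write a survival registry file
#'
#' Plain-CSV serialization of the registry (columns `stratum`, `family`,
#' `par1`, `par2`, `cap_years`), the "parameter registry" external interface.
#'
#' @param path File path.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "family", "par1", "par2", "cap_years")
  if (!all(need %in% names(df))) {
    stop("registry CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_registry
#' @param registry Registry tibble.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}
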