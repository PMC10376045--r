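#' Experimental group definitions
#'
#' The four repeated umbilical-occlusion protocols used in the near-term
#' fetal sheep experiments. Group names encode occlusion length (minutes)
#' and spacing (minutes): e.g. "N1-5" = normoxic, 1 min occlusions every
#' 5 min; "H1-5" is the chronically hypoxic arm (PaO2 < 17 mmHg for at
#' least 3 days before the experiment).
#'
#' @return A data.frame with one row per group: `name`, `n_sheep`,
#'   `condition` ("normoxic"/"hypoxic"), `occlusion_length` and
#'   `occlusion_spacing` (seconds).
#' @export
sheep_group_table <- function() {
  data.frame(
    name = c("N1-5", "H1-5", "N1-2.5", "N2-5"),
    n_sheep = c(12L, 8L, 25L, 12L),
    condition = c("normoxic", "hypoxic", "normoxic", "normoxic"),
    occlusion_length = c(60, 60, 60, 120),
    occlusion_spacing = c(300, 300, 150, 300),
    stringsAsFactors = FALSE
  )
}

#' Look up one experimental group
#'
#' @param name One of "N1-5", "H1-5", "N1-2.5", "N2-5".
#' @return A `group_spec` list with fields `name`, `n_sheep`, `condition`,
#'   `occlusion_length`, `occlusion_spacing` (seconds).
#' @export
group_spec <- function(name) {
  tab <- sheep_group_table()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown experimental group '", name, "'; expected one of ",
         paste(tab$name, collapse = ", "))
  }
  g <- as.list(tab[i, ])
  stopifnot(g$occlusion_length < g$occlusion_spacing)
  class(g) <- "group_spec"
  g
}
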