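# Repo-wide units: mm, N, N/mm^2 (= MPa). Pressures entered in mmHg must go
# through these converters; 1 mmHg = 133.322 Pa = 1.33322e-4 N/mm^2.

#' Convert a pressure from mmHg to N/mm^2 (MPa)
#'
#' All solvers in this package work in a consistent mm / N / N/mm^2 unit
#' system. Clinical pressures quoted in mmHg (e.g. systolic 120 mmHg) must be
#' converted before being passed to any solver.
#'
#' @param p_mmHg numeric vector of pressures in mmHg.
#' @return pressures in N/mm^2.
#' @examples
#' mmHg_to_MPa(120)  # ~0.016 N/mm^2, a typical systolic pressure
#' @export
mmHg_to_MPa <- function(p_mmHg) {
  stopifnot(is.numeric(p_mmHg))
  p_mmHg * 1.33322e-4
}

#' Convert a pressure from N/mm^2 (MPa) to mmHg
#'
#' @param p_MPa numeric vector of pressures in N/mm^2.
#' @return pressures in mmHg.
#' @export
MPa_to_mmHg <- function(p_MPa) {
  stopifnot(is.numeric(p_MPa))
  p_MPa / 1.33322e-4
}
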