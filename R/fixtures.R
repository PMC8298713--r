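#' Built-in deterministic test fixtures
#'
#' Tiny hand-constructed observation tables for exercising the pipeline:
#' \describe{
#'   \item{`"straight-runner"`}{one immune cell moving in a straight line at
#'     constant speed past a single stationary target; every p-value is
#'     computable by hand from the approach-cone geometry.}
#'   \item{`"gap-track"`}{one immune cell with missing frames, plus a
#'     target, exercising the triplet gap rules.}
#'   \item{`"two-class"`}{two immune and two target cells, for checking
#'     within-class (NK-NK) versus between-class pairing modes.}
#' }
#'
#' @param name fixture name.
#' @return an `observation_table` with frame interval 1.
#' @export
make_fixture <- function(name = c("straight-runner", "gap-track", "two-class")) {
  name <- match.arg(name)
  tab <- switch(name,
    "straight-runner" = {
      tt <- 0:10
      rbind(
        data.frame(t = tt, x = 10 * tt, y = 0, z = 0, id = 1, class = 0),
        data.frame(t = tt, x = 50, y = 40, z = 0, id = 2, class = 1))
    },
    "gap-track" = {
      tt <- c(0, 1, 2, 4, 5, 6, 8)
      rbind(
        data.frame(t = tt, x = 5 * tt, y = c(0, 2, 1, 3, 2, 4, 3), z = 0,
                   id = 1, class = 0),
        data.frame(t = 0:8, x = 30, y = 20, z = 0, id = 2, class = 1))
    },
    "two-class" = {
      tt <- 0:6
      rbind(
        data.frame(t = tt, x = 4 * tt, y = 0, z = 0, id = 1, class = 0),
        data.frame(t = tt, x = 4 * tt, y = 30, z = 0, id = 2, class = 0),
        data.frame(t = tt, x = 15, y = 15, z = 0, id = 3, class = 1),
        data.frame(t = tt, x = 40, y = 5, z = 0, id = 4, class = 1))
    })
  observation_table(tab, frame_interval = 1)
}
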