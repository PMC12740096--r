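#' Arena layout for the nine-arm radial maze and the open field
#'
#' The radial maze is divided into `3 * n_arms + 1` scored regions: one per
#' arm (`A0..A8`), one per bridge connecting an arm to the platform
#' (`B0..B8`), one outer-centre sector facing each bridge (`O0..O8`) and a
#' single inner-centre region (`C`) where animals are introduced. Arms are
#' numbered consecutively clockwise so that circular offset arithmetic
#' between consecutive arm entries is well defined. The open field is scored
#' as three concentric zones (centre, inner, outer).
#'
#' @param n_arms number of maze arms (default 9).
#' @return an object of class `arena_layout` with components `n_arms`,
#'   `arms`, `bridges`, `outer_centre`, `inner_centre`, `maze_regions`
#'   (all maze region ids) and `field_zones`.
#' @examples
#' layout <- arena_layout()
#' length(layout$maze_regions)  # 28
#' @export
arena_layout <- function(n_arms = 9L) {
  n_arms <- as.integer(n_arms)
  if (is.na(n_arms) || n_arms < 2L) stopf("n_arms must be an integer >= 2")
  idx <- 0:(n_arms - 1L)
  layout <- list(
    n_arms = n_arms,
    arms = paste0("A", idx),
    bridges = paste0("B", idx),
    outer_centre = paste0("O", idx),
    inner_centre = "C",
    field_zones = c("centre", "inner", "outer")
  )
  layout$maze_regions <- c(layout$arms, layout$bridges, layout$outer_centre,
                           layout$inner_centre)
  stopifnot(!anyDuplicated(layout$maze_regions),
            length(layout$maze_regions) == 3L * n_arms + 1L)
  class(layout) <- "arena_layout"
  layout
}

#' @export
print.arena_layout <- function(x, ...) {
  cat(sprintf("Arena layout: %d-arm radial maze, %d scored regions (%d arms, %d bridges, %d outer-centre, 1 inner-centre)\n",
              x$n_arms, length(x$maze_regions), x$n_arms, x$n_arms, x$n_arms))
  invisible(x)
}

# map arm region ids ("A3") to integer arm indices, with validation
arm_index <- function(region, layout) {
  m <- match(region, layout$arms)
  if (anyNA(m)) stopf("not an arm region: %s",
                      paste(unique(region[is.na(m)]), collapse = ", "))
  m - 1L
}

assert_known_regions <- function(region, layout, where = "event log") {
  bad <- setdiff(unique(region), layout$maze_regions)
  if (length(bad))
    stopf("%s contains region id(s) not in the %d-arm layout: %s",
          where, layout$n_arms, paste(bad, collapse = ", "))
  invisible(TRUE)
}
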