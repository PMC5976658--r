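#' Build the 9-target / 72-movement point-to-point task design
#'
#' Constructs the experimental design used throughout the package: nine
#' targets arranged on three vertical bars (left, middle, right) at three
#' heights (top, middle, bottom), and all 72 ordered pairs of distinct
#' targets as point-to-point movements. Each movement is annotated with ten
#' discrete task parameters: starting target (1-9), starting bar (1-3),
#' starting height (T/M/B), movement direction (8 values), horizontal
#' direction (L/R/S), vertical direction (U/D/S), end bar, end height, end
#' target, and the full movement identity (1-72).
#'
#' Conventions: targets T1-T3 lie on the top row, T4-T6 on the middle row
#' and T7-T9 on the bottom row; within a row, targets are numbered from the
#' subject's right to left, so the movement T1 to T3 is horizontal and
#' leftward, T1 to T7 is vertical downward on the same bar, and T1 to T9 is
#' diagonal (down and leftward). Bars are numbered 1 (left) to 3 (right).
#'
#' The direction parameter concatenates the vertical (U/D/S) and horizontal
#' (L/R/S) components; "SS" would be a non-movement and is excluded, leaving
#' exactly 8 direction classes.
#'
#' @return an object of class `task_design`: a list with `targets` (data
#'   frame of 9 targets with bar and height), `movements` (data frame of 72
#'   rows, one per ordered pair of distinct targets, with the 10 task
#'   parameters) and `parameters` (named list giving, for each task
#'   parameter, its class labels).
#' @examples
#' design <- build_task_design()
#' nrow(design$movements)       # 72
#' length(design$parameters$direction)  # 8
#' @export
build_task_design <- function() {
  heights <- c("T", "M", "B")
  # row-major target layout; bar 3 = rightmost, numbered right-to-left
  targets <- data.frame(
    target = paste0("T", 1:9),
    height = rep(heights, each = 3),
    bar = rep(c(3L, 2L, 1L), times = 3),
    stringsAsFactors = FALSE
  )
  pairs <- expand.grid(start = 1:9, end = 1:9)
  pairs <- pairs[pairs$start != pairs$end, , drop = FALSE]
  # order movements by starting target then end target for a stable id
  pairs <- pairs[order(pairs$start, pairs$end), , drop = FALSE]
  recs <- lapply(seq_len(nrow(pairs)), function(i) {
    task_parameter_record(pairs$start[i], pairs$end[i], targets)
  })
  movements <- do.call(rbind, recs)
  movements$movement <- seq_len(nrow(movements))
  rownames(movements) <- NULL
  params <- list(
    start_target = paste0("T", 1:9),
    start_bar = as.character(1:3),
    start_height = heights,
    direction = c("UL", "US", "UR", "SL", "SR", "DL", "DS", "DR"),
    horizontal_direction = c("L", "R", "S"),
    vertical_direction = c("U", "D", "S"),
    end_bar = as.character(1:3),
    end_height = heights,
    end_target = paste0("T", 1:9),
    movement = as.character(seq_len(nrow(movements)))
  )
  structure(list(targets = targets, movements = movements,
                 parameters = params),
            class = "task_design")
}

# One 10-parameter record for an ordered target pair (internal; inputs are
# target indices 1..9 and the target layout table).
task_parameter_record <- function(start, end, targets) {
  hs <- targets$height[start]
  he <- targets$height[end]
  bs <- targets$bar[start]
  be <- targets$bar[end]
  lvl <- c(T = 3L, M = 2L, B = 1L)
  vert <- if (lvl[[he]] > lvl[[hs]]) "U" else if (lvl[[he]] < lvl[[hs]]) "D" else "S"
  horiz <- if (be < bs) "L" else if (be > bs) "R" else "S"
  data.frame(
    start_target = targets$target[start],
    start_bar = as.character(bs),
    start_height = hs,
    direction = paste0(vert, horiz),
    horizontal_direction = horiz,
    vertical_direction = vert,
    end_bar = as.character(be),
    end_height = he,
    end_target = targets$target[end],
    stringsAsFactors = FALSE
  )
}

#' Derive the ten task parameters of a single movement
#'
#' @param start_target,end_target target identifiers ("T1".."T9") present in
#'   the design. The start and end must differ (same-target pairs are not
#'   movements of this design).
#' @param design a [build_task_design()] object.
#' @return a one-row data frame with the 10 task-parameter columns
#'   (including the `movement` id), identical to the matching row of
#'   `design$movements`.
#' @export
derive_task_parameters <- function(start_target, end_target,
                                   design = build_task_design()) {
  stopifnot(inherits(design, "task_design"))
  ids <- design$targets$target
  if (!(start_target %in% ids) || !(end_target %in% ids)) {
    stop("unknown target identifier")
  }
  if (identical(start_target, end_target)) {
    stop("start and end target must differ: same-target pairs are not movements")
  }
  row <- design$movements[design$movements$start_target == start_target &
                            design$movements$end_target == end_target, ,
                          drop = FALSE]
  rownames(row) <- NULL
  row
}

#' @export
print.task_design <- function(x, ...) {
  cat("Point-to-point task design: 9 targets (3 bars x 3 heights),",
      nrow(x$movements), "movements\n")
  cat("Task parameters:", paste(names(x$parameters), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the ten task-parameter columns, in canonical order
#'
#' @return character vector of the 10 task-parameter names (starting
#'   target/bar/height, direction, horizontal/vertical direction, end
#'   bar/height/target, full movement id).
#' @export
task_parameter_names <- function() {
  c("start_target", "start_bar", "start_height", "direction",
    "horizontal_direction", "vertical_direction", "end_bar", "end_height",
    "end_target", "movement")
}
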