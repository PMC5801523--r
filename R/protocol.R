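#' The six-condition BAM standing-balance protocol
#'
#' Returns the protocol definition used throughout the package: six quiet
#' standing conditions of 60 seconds each, crossing support surface (firm or
#' foam), stance (feet together or tandem) and vision (eyes open or closed).
#' Conditions 1-2 are feet together on a firm surface (eyes open, closed),
#' 3-4 feet together on foam, and 5-6 tandem stance on a firm surface.
#'
#' @param duration_s Stance duration in seconds (default 60).
#' @return A data frame of class `bam_protocol` with columns `condition`,
#'   `surface`, `stance`, `eyes`, `duration_s` and a short `label`.
#' @examples
#' bam_protocol()
#' @export
bam_protocol <- function(duration_s = 60) {
  p <- data.frame(
    condition = 1:6,
    surface = c("firm", "firm", "foam", "foam", "firm", "firm"),
    stance = c("feet_together", "feet_together", "feet_together",
               "feet_together", "tandem", "tandem"),
    eyes = c("open", "closed", "open", "closed", "open", "closed"),
    duration_s = duration_s,
    stringsAsFactors = FALSE
  )
  p$label <- paste0(p$surface, "/", p$stance, "/", "eyes_", p$eyes)
  class(p) <- c("bam_protocol", "data.frame")
  p
}

#' Facilitator-recorded trial failure reasons
#'
#' The six protocol violations a study facilitator records, any of which
#' invalidates a trial: (1) arms came off the chest, (2) knees bent,
#' (3) feet moved out of position, (4) bent forward at the waist more than
#' 45 degrees, (5) eyes opened during an eyes-closed stance, (6) subject
#' declined the stance.
#'
#' @return Character vector of the six canonical failure-reason codes.
#' @export
failure_reasons <- function() {
  c("arms_off_chest", "knees_bent", "feet_moved", "bent_forward",
    "eyes_opened", "declined")
}

#' Device axis conventions
#'
#' Maps the sensor's x/y/z axes onto body axes (anterior-posterior,
#' mediolateral, vertical) for a given mounting. Each mapping carries a sign
#' so that flipped mountings can be expressed. The three body axes must use
#' three distinct sensor axes.
#'
#' @param device `"head"` or `"waist"`.
#' @param ap,ml,vertical Signed axis names, e.g. `"z"`, `"-x"`.
#' @return An object of class `axis_convention`.
#' @examples
#' axis_convention("waist", ap = "z", ml = "x", vertical = "y")
#' @export
axis_convention <- function(device = c("waist", "head"),
                            ap = "z", ml = "x", vertical = "y") {
  device <- match.arg(device)
  parse_axis <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    sign <- if (startsWith(s, "-")) -1 else 1
    ax <- sub("^[+-]", "", s)
    if (!ax %in% c("x", "y", "z"))
      stop("axis must be one of x, y, z (optionally signed), got: ", s)
    list(axis = ax, sign = sign)
  }
  conv <- list(device = device, ap = parse_axis(ap), ml = parse_axis(ml),
               vertical = parse_axis(vertical))
  axes <- c(conv$ap$axis, conv$ml$axis, conv$vertical$axis)
  if (anyDuplicated(axes))
    stop("axis convention reuses a sensor axis: ", paste(axes, collapse = ","))
  class(conv) <- "axis_convention"
  conv
}

#' Default axis conventions for the two study devices
#'
#' The waist smartphone is worn upright with the screen facing away from the
#' subject, so its screen normal (z) is the anterior-posterior axis and its
#' long axis (y) is vertical. The head device uses the same mapping: the
#' low-pass filtered z axis carries AP sway. Conventions are configuration,
#' not hard-coded, because mountings vary.
#'
#' @return Named list with elements `waist` and `head`.
#' @export
default_conventions <- function() {
  list(waist = axis_convention("waist", ap = "z", ml = "x", vertical = "y"),
       head = axis_convention("head", ap = "z", ml = "x", vertical = "y"))
}

#' @export
print.axis_convention <- function(x, ...) {
  fmt <- function(a) paste0(if (a$sign < 0) "-" else "+", a$axis)
  cat(sprintf("Axis convention [%s]: AP=%s ML=%s vertical=%s\n",
              x$device, fmt(x$ap), fmt(x$ml), fmt(x$vertical)))
  invisible(x)
}
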