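#' Joint schemas
#'
#' A joint schema fixes the ordered set of tracked body joints (`Nb` of them)
#' and records which two entries are the ankles, since the inter-ankle
#' distance drives gait-cycle segmentation. [kinect20_schema()] is the
#' canonical 20-joint skeleton of the first-generation Kinect sensor and is
#' the package default everywhere.
#'
#' @param names Character vector of unique joint labels, in sensor order.
#' @param left_ankle,right_ankle Position (1-based) or label of each ankle.
#' @return An object of class `joint_schema`: a list with elements `names`,
#'   `n_joints`, `left_ankle`, `right_ankle` (both integer positions).
#' @examples
#' sch <- kinect20_schema()
#' sch$n_joints
#' @export
joint_schema <- function(names, left_ankle, right_ankle) {
  names <- as.character(names)
  if (length(names) < 2L) {
    abort("A joint schema needs at least two joints.")
  }
  if (anyDuplicated(names)) {
    abort("Joint names must be unique.")
  }
  la <- resolve_joint(left_ankle, names, "left_ankle")
  ra <- resolve_joint(right_ankle, names, "right_ankle")
  structure(
    list(names = names, n_joints = length(names),
         left_ankle = la, right_ankle = ra),
    class = "joint_schema"
  )
}

resolve_joint <- function(x, names, what) {
  if (is.character(x)) {
    i <- match(x, names)
    if (is.na(i)) abort(sprintf("%s '%s' is not a joint in the schema.", what, x))
    return(as.integer(i))
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1L || i > length(names)) {
    abort(sprintf("%s index %s is out of range 1..%d.", what, x, length(names)))
  }
  i
}

#' @rdname joint_schema
#' @export
kinect20_schema <- function() {
  joint_schema(
    c("HipCenter", "Spine", "ShoulderCenter", "Head",
      "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
      "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
      "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
      "HipRight", "KneeRight", "AnkleRight", "FootRight"),
    left_ankle = "AnkleLeft", right_ankle = "AnkleRight"
  )
}

#' @export
print.joint_schema <- function(x, ...) {
  cat(sprintf("<joint_schema: %d joints; ankles = %s / %s>\n",
              x$n_joints, x$names[x$left_ankle], x$names[x$right_ankle]))
  invisible(x)
}
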