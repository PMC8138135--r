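#' Canonical 25-joint map for Kinect-v2-style skeletons
#'
#' Returns the index-to-role mapping used throughout the package. Indices
#' 1..25 map bijectively onto anatomical labels. Eleven roles are load-bearing
#' for the pipeline (head, neck, clavicle, both shoulders, spine, both wrists,
#' both feet, left toe); the remaining indices carry conventional Kinect v2
#' joint names and are processed but never singled out by any feature.
#'
#' Joints 22/23 are modelled as the left/right foot markers used for stride
#' length and toe clearance; joint 24 is the left-toe marker whose vertical
#' trajectory defines gait-cycle (toe-off) boundaries.
#'
#' @return Named character vector of length 25; names are the indices
#'   "1".."25", values the anatomical roles.
#' @export
#' @examples
#' kinect_joint_map()[["9"]]  # "spine"
kinect_joint_map <- function() {
  roles <- c(
    "head", "neck", "clavicle", "shoulder_left", "shoulder_right",
    "elbow_left", "elbow_right", "hand_left", "spine", "wrist_left",
    "hand_right", "thumb_left", "thumb_right", "wrist_right",
    "hip_left", "hip_right", "knee_left", "knee_right",
    "ankle_left", "ankle_right", "spine_base",
    "foot_left", "foot_right", "toe_left", "toe_right"
  )
  stats::setNames(roles, as.character(1:25))
}

#' @rdname kinect_joint_map
#' @format NULL
#' @export
JOINT_MAP_VERSION <- "1"

#' Look up a joint index by anatomical role
#'
#' @param role Anatomical label, e.g. "spine" or "toe_left".
#' @return Integer joint index in 1..25.
#' @export
joint_index <- function(role) {
  jm <- kinect_joint_map()
  i <- match(role, jm)
  if (is.na(i)) stop("unknown joint role: ", role, call. = FALSE)
  as.integer(names(jm)[i])
}
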