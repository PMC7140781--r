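# Canonical 51-joint skinning layout: 5 trunk, 2 neck/head, 4 per leg,
# 3 per arm, 15 per hand (3 per finger).

canonical_fingers <- function(side) {
  fingers <- c("thumb", "index", "middle", "ring", "pinky")
  as.vector(t(outer(fingers, 1:3, function(f, k) paste0(side, "_", f, k))))
}

#' The canonical 51-joint naming
#'
#' One fixed joint list used as the common vocabulary across skeleton
#' formats: 5 trunk joints, neck and head, 4 joints per leg, 3 per arm and
#' 15 finger joints per hand. Lower-resolution skeletons (e.g. the 26-joint
#' annotation skeleton typical for video material) map onto a subset of
#' these names through the nomenclature table.
#'
#' @return Character vector of 51 joint names.
#' @export
canonical_joints <- function() {
  c("hips", "spine", "spine1", "spine2", "chest",
    "neck", "head",
    "left_upleg", "left_leg", "left_foot", "left_toe",
    "right_upleg", "right_leg", "right_foot", "right_toe",
    "left_arm", "left_forearm", "left_hand",
    "right_arm", "right_forearm", "right_hand",
    canonical_fingers("left"), canonical_fingers("right"))
}

#' Joint nomenclature translation table
#'
#' Maps body-part names from the naming schemes of the major animation and
#' capture products (MotionBuilder, Mixamo, Unity humanoid, Kinect) onto
#' the canonical joint list. Only the commonly exported core-body names are
#' covered; finger naming is already canonical-like in most products and is
#' normalized by pattern.
#'
#' @return Tibble with columns `alias` and `canonical`.
#' @export
joint_nomenclature <- function() {
  mb <- c(Hips = "hips", Spine = "spine", Spine1 = "spine1", Spine2 = "spine2",
          Spine3 = "chest", Chest = "chest", Neck = "neck", Head = "head",
          LeftUpLeg = "left_upleg", LeftLeg = "left_leg", LeftFoot = "left_foot",
          LeftToeBase = "left_toe", RightUpLeg = "right_upleg",
          RightLeg = "right_leg", RightFoot = "right_foot",
          RightToeBase = "right_toe", LeftArm = "left_arm",
          LeftForeArm = "left_forearm", LeftHand = "left_hand",
          RightArm = "right_arm", RightForeArm = "right_forearm",
          RightHand = "right_hand", LeftShoulder = "left_arm",
          RightShoulder = "right_arm")
  unity <- c(LeftUpperLeg = "left_upleg", LeftLowerLeg = "left_leg",
             RightUpperLeg = "right_upleg", RightLowerLeg = "right_leg",
             LeftUpperArm = "left_arm", LeftLowerArm = "left_forearm",
             RightUpperArm = "right_arm", RightLowerArm = "right_forearm",
             LeftToes = "left_toe", RightToes = "right_toe",
             UpperChest = "chest")
  kinect <- c(SpineBase = "hips", SpineMid = "spine1", SpineShoulder = "chest",
              Neck = "neck", Head = "head", HipLeft = "left_upleg",
              KneeLeft = "left_leg", AnkleLeft = "left_foot",
              FootLeft = "left_toe", HipRight = "right_upleg",
              KneeRight = "right_leg", AnkleRight = "right_foot",
              FootRight = "right_toe", ShoulderLeft = "left_arm",
              ElbowLeft = "left_forearm", WristLeft = "left_hand",
              ShoulderRight = "right_arm", ElbowRight = "right_forearm",
              WristRight = "right_hand")
  base <- c(mb, unity, kinect)
  tab <- tibble(alias = names(base), canonical = unname(base))
  # Mixamo prefixes the MotionBuilder-style names
  mixamo <- tibble(alias = paste0("mixamorig:", names(mb)),
                   canonical = unname(mb))
  dplyr::distinct(dplyr::bind_rows(tab, mixamo), alias, .keep_all = TRUE)
}

#' Normalize joint labels onto the canonical naming
#'
#' Labels already canonical pass through; known aliases from the
#' nomenclature table are translated (case-insensitively); unknown
#' non-empty labels are kept verbatim with a warning. Empty strings (gaze
#' off the character) always pass through silently.
#'
#' @param labels Character vector of joint labels.
#' @param quiet Suppress the unknown-label warning.
#' @return Character vector of normalized labels.
#' @export
normalize_joint_labels <- function(labels, quiet = FALSE) {
  out <- as.character(labels)
  out[is.na(out)] <- ""
  canon <- canonical_joints()
  tab <- joint_nomenclature()
  lower <- tolower(out)
  is_canon <- lower %in% canon
  out[is_canon] <- lower[is_canon]
  idx <- match(tolower(out), tolower(tab$alias))
  hit <- !is.na(idx) & !is_canon
  out[hit] <- tab$canonical[idx[hit]]
  unknown <- nzchar(out) & !(out %in% canon)
  if (any(unknown) && !quiet) {
    warn(paste0("unknown joint label(s) kept verbatim: ",
                paste(unique(out[unknown]), collapse = ", ")),
         class = "skelgaze_unknown_joint")
  }
  out
}
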