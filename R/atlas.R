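#' Build the standard 11-region atlas from a label-to-lobe mapping
#'
#' Cortical measurements are reported for 11 regions: the four lobes
#' (frontal, parietal, temporal, occipital) per hemisphere, each hemisphere,
#' and the whole brain. The label-to-lobe assignment follows whatever
#' segmentation convention produced the input volume (e.g. FreeSurfer lobar
#' grouping) and is supplied by the user as a mapping; hemisphere and
#' whole-brain label sets are exact unions of their lobar parts.
#'
#' @param label_map a data frame with columns `label` (integer), `lobe`
#'   (one of `"frontal"`, `"parietal"`, `"temporal"`, `"occipital"`) and
#'   `hemisphere` (`"left"` or `"right"`), or a named list as read by
#'   [read_atlas()].
#' @return A tibble with one row per region and columns `name`, `kind`
#'   (`"lobe"`, `"hemisphere"`, `"whole_brain"`), `hemisphere` (`"left"`,
#'   `"right"`, `"both"`) and `label_ids` (list-column of integer vectors).
#'   Exactly 11 rows: 8 lobes, `LH`, `RH`, `WB`.
#' @examples
#' lm <- tibble::tibble(
#'   label = 1:8,
#'   lobe = rep(c("frontal", "parietal", "temporal", "occipital"), 2),
#'   hemisphere = rep(c("left", "right"), each = 4)
#' )
#' default_region_atlas(lm)
#' @export
default_region_atlas <- function(label_map) {
  label_map <- as_tibble(label_map)
  stopifnot(all(c("label", "lobe", "hemisphere") %in% names(label_map)))
  label_map$label <- as.integer(label_map$label)
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  hemis <- c("left", "right")
  bad_lobe <- setdiff(unique(label_map$lobe), lobes)
  if (length(bad_lobe) > 0) {
    abort(paste0("Unknown lobe name(s): ", paste(bad_lobe, collapse = ", ")))
  }
  bad_h <- setdiff(unique(label_map$hemisphere), hemis)
  if (length(bad_h) > 0) {
    abort(paste0("Unknown hemisphere(s): ", paste(bad_h, collapse = ", ")))
  }
  dup <- label_map$label[duplicated(label_map$label)]
  if (length(dup) > 0) {
    abort(paste0("Label(s) mapped more than once: ",
                 paste(unique(dup), collapse = ", ")))
  }

  hemi_short <- c(left = "LH", right = "RH")
  lobe_rows <- list()
  for (h in hemis) {
    for (lb in lobes) {
      ids <- label_map$label[label_map$lobe == lb & label_map$hemisphere == h]
      nm <- paste0(toupper(substring(lb, 1, 1)), substring(lb, 2), " ",
                   hemi_short[[h]])
      if (length(ids) == 0) {
        abort(paste0("Region '", nm, "' has no labels assigned in the atlas mapping."))
      }
      lobe_rows[[nm]] <- tibble(
        name = nm, kind = "lobe", hemisphere = h,
        label_ids = list(sort(ids))
      )
    }
  }
  lobe_tbl <- dplyr::bind_rows(lobe_rows)
  hemi_tbl <- dplyr::bind_rows(
    tibble(name = "LH", kind = "hemisphere", hemisphere = "left",
           label_ids = list(sort(label_map$label[label_map$hemisphere == "left"]))),
    tibble(name = "RH", kind = "hemisphere", hemisphere = "right",
           label_ids = list(sort(label_map$label[label_map$hemisphere == "right"])))
  )
  wb_tbl <- tibble(name = "WB", kind = "whole_brain", hemisphere = "both",
                   label_ids = list(sort(label_map$label)))
  dplyr::bind_rows(lobe_tbl, hemi_tbl, wb_tbl)
}

#' Read an atlas label mapping from JSON or YAML
#'
#' The file maps integer labels (as keys) to a lobe and hemisphere, e.g.
#' `{"3": {"lobe": "frontal", "hemisphere": "left"}, ...}`. A documented
#' example ships with the package:
#' `system.file("extdata", "atlas_8lobe_example.json", package = "ribbonfd")`.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` mapping file.
#' @return A tibble with columns `label`, `lobe`, `hemisphere`, suitable for
#'   [default_region_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Atlas file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  if (length(raw) == 0) abort(paste0("Atlas file is empty: ", path))
  keys <- suppressWarnings(as.integer(names(raw)))
  if (anyNA(keys)) {
    abort("Atlas keys must be integer labels (as strings).")
  }
  tibble(
    label = keys,
    lobe = unname(purrr::map_chr(raw, "lobe")),
    hemisphere = unname(purrr::map_chr(raw, "hemisphere"))
  )
}
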