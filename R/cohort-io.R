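# On-disk layout of a synthetic cohort: NIfTI volumes + masks, CSV blood and
# growth tables, and a JSON manifest tying them together.

#' Write a synthetic cohort to disk
#'
#' Emits one NIfTI volume and mask per animal/modality/flank, a `cbc.csv`
#' (one row per animal), a long-format `growth.csv`, and a `manifest.json`
#' listing ids, arms, labels and every file written. Re-reading with
#' [read_cohort()] reproduces masks bit-exactly and volumes within float32
#' precision.
#'
#' @param cohort list of `synthetic_animal` records from [generate_cohort()]
#'   (with images).
#' @param out_dir output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir), call. = FALSE)
  cbc_rows <- list(); growth_rows <- list(); manifest <- list()
  for (a in cohort) {
    entry <- list(animal_id = a$animal_id, arm = a$arm,
                  abscopal = if (is.na(a$abscopal)) NULL else a$abscopal,
                  files = list())
    if (!is.null(a$tumors)) {
      for (key in names(a$tumors)) {
        tu <- a$tumors[[key]]
        vf <- file.path(out_dir, sprintf("%s_%s.nii.gz", a$animal_id, key))
        mf <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz", a$animal_id, key))
        write_volume(tu$volume, vf)
        write_volume(tu$roi, mf, spacing = tu$volume$spacing)
        entry$files[[key]] <- list(volume = basename(vf), mask = basename(mf),
                                   modality = tu$volume$modality)
      }
    }
    cb <- a$cbc
    cbc_rows[[length(cbc_rows) + 1L]] <- data.frame(
      animal_id = cb$animal_id, wbc = cb$wbc, neutrophils = cb$neutrophils,
      lymphocytes = cb$lymphocytes, monocytes = cb$monocytes,
      eosinophils = cb$eosinophils, basophils = cb$basophils, rbc = cb$rbc)
    for (fl in c("left", "right")) {
      g <- a$growth[[fl]]
      growth_rows[[length(growth_rows) + 1L]] <-
        g[, c("animal_id", "flank", "day", "width_mm", "length_mm")]
    }
    manifest[[length(manifest) + 1L]] <- entry
  }
  utils::write.csv(do.call(rbind, cbc_rows), file.path(out_dir, "cbc.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, growth_rows), file.path(out_dir, "growth.csv"),
                   row.names = FALSE)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(animals = manifest), mpath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(mpath)
}

#' Read a cohort back from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by [write_cohort()].
#' @return A list of animal records mirroring [generate_cohort()] output
#'   (without the latent `planted` values, which are not persisted).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  dir_ <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path)
  cbc <- utils::read.csv(file.path(dir_, "cbc.csv"))
  growth <- utils::read.csv(file.path(dir_, "growth.csv"))
  lapply(man$animals, function(e) {
    aid <- e$animal_id
    tumors <- NULL
    if (length(e$files)) {
      tumors <- list()
      for (key in names(e$files)) {
        f <- e$files[[key]]
        vol <- load_volume(file.path(dir_, f$volume), modality = f$modality)
        fl <- sub("^(ct|mri)_", "", key)
        roi <- load_mask(file.path(dir_, f$mask), vol, animal_id = aid, flank = fl)
        tumors[[key]] <- list(volume = vol, roi = roi)
      }
    }
    cb <- cbc[cbc$animal_id == aid, ]
    gr <- lapply(c(left = "left", right = "right"), function(fl) {
      g <- growth[growth$animal_id == aid & growth$flank == fl, ]
      growth_record(aid, fl, g$day, g$width_mm, g$length_mm)
    })
    structure(list(animal_id = aid, arm = e$arm,
                   abscopal = e$abscopal %||% NA, cbc = cbc_panel(
                     aid, cb$wbc, cb$neutrophils, cb$lymphocytes, cb$monocytes,
                     cb$eosinophils, cb$basophils, cb$rbc),
                   growth = gr, tumors = tumors),
              class = "synthetic_animal")
  })
}
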