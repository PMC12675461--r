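# Seeded, stratified, copy-based partition of a class-folder image tree into
# train/validation/test subsets. Per-class counts use integer truncation of
# ratio * available (the rule that reproduces a 376-image test split from a
# 2,513-image class at ratio 0.15), and file lists are sorted
# lexicographically (C locale) before shuffling so results do not depend on
# filesystem enumeration order.

#' Split specification
#'
#' @param ratios Named or unnamed length-3 numeric vector of train/val/test
#'   fractions, each in `[0, 1]`, summing to at most 1.
#' @param seed Integer seed for the selection RNG (default 42).
#' @param source Directory with one sub-folder per class.
#' @param target Directory to receive `subset/class/` copies.
#' @param paper_mode If `TRUE`, each subset is drawn by an independent
#'   sampling pass over the full class list (the literal sequential-
#'   invocation design, which can re-select a file into two subsets); the
#'   default `FALSE` slices one shuffle per class, guaranteeing disjointness.
#' @param link If `TRUE`, hard-link instead of copy (test convenience).
#' @return A `split_spec` list.
#' @export
split_spec <- function(ratios = c(train = 0.7, val = 0.15, test = 0.15),
                       seed = 42L, source, target,
                       paper_mode = FALSE, link = FALSE) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 3L) {
    abort("`ratios` must have exactly 3 entries (train, val, test).",
      class = "sobelnet_error_validation")
  }
  if (any(ratios < 0) || any(ratios > 1)) {
    abort("Each split ratio must lie in [0, 1].", class = "sobelnet_error_validation")
  }
  if (sum(ratios) > 1 + 1e-9) {
    abort("Split ratios must sum to at most 1.", class = "sobelnet_error_validation")
  }
  structure(list(
    ratios = setNames(ratios, c("train", "val", "test")),
    seed = as.integer(seed), source = source, target = target,
    paper_mode = isTRUE(paper_mode), link = isTRUE(link)
  ), class = "split_spec")
}

list_class_files <- function(source) {
  classes <- sort(list.dirs(source, full.names = FALSE, recursive = FALSE),
    method = "radix")
  classes <- classes[nzchar(classes)]
  if (length(classes) == 0L) {
    abort(sprintf("No class folders found under '%s'.", source),
      class = "sobelnet_error_validation")
  }
  files <- lapply(classes, function(cl) {
    f <- list.files(file.path(source, cl))
    f <- f[!grepl("\\.tsv$", f)]
    sort(f, method = "radix")
  })
  names(files) <- classes
  empty <- names(files)[lengths(files) == 0L]
  if (length(empty) > 0L) {
    abort(sprintf("Class folder(s) with no files: %s.", paste(empty, collapse = ", ")),
      class = "sobelnet_error_validation")
  }
  files
}

#' Partition a class-folder dataset into train/val/test
#'
#' Selection is uniform without replacement within each class via a
#' generator seeded from `spec$seed`; the per-subset, per-class count is
#' `trunc(ratio * n_class)` capped at the number available. Files are copied
#' into `target/<subset>/<class>/`.
#'
#' @param spec A [split_spec()].
#' @return A `split_manifest` tibble with columns `subset`, `class`, `file`;
#'   attributes `spec` and `target`.
#' @export
split_dataset <- function(spec) {
  stopifnot(inherits(spec, "split_spec"))
  files <- list_class_files(spec$source)
  subsets <- names(spec$ratios)
  sel <- list()
  with_seed(spec$seed, {
    if (spec$paper_mode) {
      for (ss in subsets) {
        for (cl in names(files)) {
          n <- length(files[[cl]])
          k <- min(trunc(spec$ratios[[ss]] * n), n)
          sel[[paste(ss, cl, sep = "\r")]] <- sample(files[[cl]], k)
        }
      }
    } else {
      for (cl in names(files)) {
        n <- length(files[[cl]])
        ks <- pmin(trunc(spec$ratios * n), n)
        perm <- sample(files[[cl]], n)
        off <- 0L
        for (ss in subsets) {
          k <- ks[[ss]]
          take <- min(k, n - off)
          sel[[paste(ss, cl, sep = "\r")]] <- if (take > 0L) perm[(off + 1L):(off + take)] else character()
          off <- off + take
        }
      }
    }
  })
  rows <- purrr::imap(sel, function(fs, key) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    tibble(subset = parts[1L], class = parts[2L], file = fs)
  })
  manifest <- dplyr::bind_rows(rows)
  for (i in seq_len(nrow(manifest))) {
    dest_dir <- file.path(spec$target, manifest$subset[i], manifest$class[i])
    if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
    src <- file.path(spec$source, manifest$class[i], manifest$file[i])
    dst <- file.path(dest_dir, manifest$file[i])
    ok <- if (spec$link) suppressWarnings(file.link(src, dst)) else file.copy(src, dst, overwrite = TRUE)
    if (!ok && !file.exists(dst)) {
      abort(sprintf("Failed to copy '%s' to '%s'.", src, dst), class = "sobelnet_error_io")
    }
  }
  # make sure empty subset/class folders exist, per the directory contract
  for (ss in subsets) {
    for (cl in names(files)) {
      d <- file.path(spec$target, ss, cl)
      if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    }
  }
  utils::write.table(manifest, file.path(spec$target, "split_manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  structure(manifest, spec = spec, target = spec$target,
    class = c("split_manifest", class(manifest)))
}

#' Verify a split manifest against the filesystem
#'
#' Reports (never raises) three violation kinds: a file assigned to more
#' than one subset within a class (`overlap`), a per-subset class count
#' differing from `trunc(ratio * n)` (`count`, only when the spec is
#' attached), and manifest entries missing on disk (`missing`).
#'
#' @param manifest A `split_manifest` (or plain tibble with `subset`,
#'   `class`, `file`), with `target` attribute or `target` argument.
#' @param target Root of the copied tree; defaults to the manifest attribute.
#' @return Tibble of violations with columns `type`, `class`, `subset`,
#'   `file`, `detail`; zero rows for a valid split.
#' @export
verify_split <- function(manifest, target = attr(manifest, "target")) {
  viol <- list()
  add <- function(type, class = NA, subset = NA, file = NA, detail = "") {
    viol[[length(viol) + 1L]] <<- tibble(
      type = type, class = as.character(class), subset = as.character(subset),
      file = as.character(file), detail = detail)
  }
  for (cl in unique(manifest$class)) {
    sub <- manifest[manifest$class == cl, ]
    dup <- sub$file[duplicated(sub$file)]
    for (f in unique(dup)) {
      in_sets <- sub$subset[sub$file == f]
      add("overlap", cl, paste(in_sets, collapse = "+"), f,
        "file assigned to multiple subsets")
    }
  }
  spec <- attr(manifest, "spec")
  if (!is.null(spec)) {
    files <- tryCatch(list_class_files(spec$source), error = function(e) NULL)
    if (!is.null(files)) {
      for (cl in names(files)) {
        n <- length(files[[cl]])
        for (ss in names(spec$ratios)) {
          expected <- min(trunc(spec$ratios[[ss]] * n), n)
          got <- sum(manifest$class == cl & manifest$subset == ss)
          if (got != expected) {
            add("count", cl, ss, NA,
              sprintf("expected %d files, manifest lists %d", expected, got))
          }
        }
      }
    }
  }
  if (!is.null(target)) {
    paths <- file.path(target, manifest$subset, manifest$class, manifest$file)
    miss <- !file.exists(paths)
    for (i in which(miss)) {
      add("missing", manifest$class[i], manifest$subset[i], manifest$file[i],
        "listed in manifest but absent on disk")
    }
  }
  out <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble(type = character(), class = character(), subset = character(),
      file = character(), detail = character())
  out
}
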