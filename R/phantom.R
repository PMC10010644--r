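# Deterministic chest-phantom simulator.
#
# Produces desk-scale stand-ins for X-ray/report pairs: a fixed parametric
# torso/lung/heart template plus zero or more localized "pathology" blobs,
# together with a rule-generated report whose label tokens are prepended to
# the text (emulating label-prefixed ground-truth reports).  Every sample is
# a pure function of (spec$seed, index), so datasets are reproducible under
# random access.

PHANTOM_KINDS <- c("opacity_left", "opacity_right", "enlarged_heart",
                   "device_line", "none")

# Surface variants per pathology; every variant contains the kind's
# localization keyword so the attention step for a lesion is well defined.
phantom_grammar <- function() {
  list(
    opacity_left = list(
      keyword = "left",
      phrase = "left lung opacity",
      variants = c("there is a focal opacity in the left lung",
                   "patchy opacity is seen in the left lung",
                   "the left lung shows an area of increased opacity")),
    opacity_right = list(
      keyword = "right",
      phrase = "right lung opacity",
      variants = c("there is a focal opacity in the right lung",
                   "patchy opacity is seen in the right lung",
                   "the right lung shows an area of increased opacity")),
    enlarged_heart = list(
      keyword = "heart",
      phrase = "an enlarged heart",
      variants = c("the heart is enlarged",
                   "the heart size is increased",
                   "the heart appears enlarged")),
    device_line = list(
      keyword = "line",
      phrase = "a support device",
      variants = c("a support line projects over the chest",
                   "a device line overlies the chest",
                   "the line of a support device is seen over the chest")),
    none = list(
      keyword = "no",
      phrase = "no acute cardiopulmonary abnormality",
      variants = "no acute cardiopulmonary abnormality")
  )
}

#' Specification of a phantom corpus
#'
#' Defines the study conditions of the synthetic corpus: image geometry,
#' the closed catalogue of pathology kinds, how many lesions an image may
#' carry, the additive noise level and the master seed.  The whole corpus is
#' a pure function of this object.
#'
#' @param image_size Side of the square image in pixels.
#' @param catalogue Character vector of pathology kinds; must be a subset of
#'   the built-in kinds (`opacity_left`, `opacity_right`, `enlarged_heart`,
#'   `device_line`, `none`).
#' @param max_pathologies Maximum number of lesions planted per image.
#' @param noise_sigma Standard deviation of the additive Gaussian pixel
#'   noise, in gray-level units of the [0,1] range.
#' @param seed Integer master seed; per-sample seeds are hashed from it.
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(seed = 1)
#' s <- generate_phantom(spec, 0)
#' dim(s$image)
phantom_spec <- function(image_size = 224L,
                         catalogue = PHANTOM_KINDS,
                         max_pathologies = 2L,
                         noise_sigma = 0.03,
                         seed = 1L) {
  if (image_size <= 0) stop("image_size must be positive")
  if (length(catalogue) == 0) stop("catalogue must be non-empty")
  unknown <- setdiff(catalogue, PHANTOM_KINDS)
  if (length(unknown) > 0) {
    stop("unknown pathology kind(s) in catalogue: ",
         paste(unknown, collapse = ", "))
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 catalogue = catalogue,
                 max_pathologies = as.integer(max_pathologies),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic 31-bit per-sample seed from (seed, index).
phantom_sample_seed <- function(seed, index) {
  h <- (as.double(seed) %% 2147483647) * 48271 +
    as.double(index) * 69621 + 1013904223
  as.integer(h %% 2147483647)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Fixed anatomy template; returns the lesion-free image (no noise).
phantom_template <- function(S) {
  xs <- matrix(rep(seq_len(S), each = S), S) / S   # column coordinate
  ys <- matrix(rep(seq_len(S), times = S), S) / S  # row coordinate
  inside <- function(cx, cy, ax, ay) {
    ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
  }
  img <- matrix(0.08, S, S) + 0.04 * ys
  img[inside(0.50, 0.55, 0.42, 0.46)] <- 0.55
  img[inside(0.32, 0.48, 0.16, 0.26)] <- 0.25
  img[inside(0.68, 0.48, 0.16, 0.26)] <- 0.25
  img[inside(0.54, 0.62, 0.14, 0.17)] <- 0.65
  img
}

# Draw lesion parameters and return list(add = additive image, mask).
phantom_lesion <- function(kind, S) {
  xs <- matrix(rep(seq_len(S), each = S), S) / S
  ys <- matrix(rep(seq_len(S), times = S), S) / S
  if (kind %in% c("opacity_left", "opacity_right")) {
    cx <- if (kind == "opacity_left") stats::runif(1, 0.26, 0.38)
          else stats::runif(1, 0.62, 0.74)
    cy <- stats::runif(1, 0.36, 0.58)
    r <- stats::runif(1, 0.055, 0.085)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    add <- 0.35 * exp(-d2 / (2 * (r / 1.8)^2))
    mask <- d2 <= r^2
  } else if (kind == "enlarged_heart") {
    f <- stats::runif(1, 1.35, 1.6)
    q <- ((xs - 0.54) / (0.14 * f))^2 + ((ys - 0.62) / (0.17 * f))^2
    add <- 0.30 * pmax(1 - q, 0)^0.7
    mask <- q <= 1
  } else if (kind == "device_line") {
    x1 <- stats::runif(1, 0.15, 0.30); y1 <- stats::runif(1, 0.25, 0.45)
    x2 <- stats::runif(1, 0.70, 0.85); y2 <- stats::runif(1, 0.45, 0.70)
    w <- stats::runif(1, 0.008, 0.014)
    vx <- x2 - x1; vy <- y2 - y1
    tt <- pmin(pmax(((xs - x1) * vx + (ys - y1) * vy) /
                      (vx * vx + vy * vy), 0), 1)
    d2 <- (xs - (x1 + tt * vx))^2 + (ys - (y1 + tt * vy))^2
    add <- 0.4 * (d2 <= w^2)
    mask <- d2 <= w^2
  } else {
    stop("unknown pathology kind: ", kind)
  }
  list(add = add, mask = mask)
}

#' Generate one phantom sample
#'
#' Deterministic in `(spec$seed, index)`: the same pair always yields a
#' bit-identical image and report.  The report is assembled from a template
#' grammar (one findings sentence per lesion, a fixed normal sentence when no
#' lesion is planted) and the label tokens are prepended to the text.
#'
#' @param spec A [phantom_spec()].
#' @param index Non-negative integer sample index.
#' @param noise Set `FALSE` to render the noise-free image (used for
#'   contrast checks).
#' @return A `phantom_sample` list: `image` (matrix in \[0,1\]), `report`
#'   (label-prefixed text), `impression`, `findings`, `labels`, `masks`
#'   (named list of logical matrices), `keywords` (localization word per
#'   lesion), `sample_id`.
#' @export
generate_phantom <- function(spec, index, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (index < 0) stop("index must be >= 0")
  gr <- phantom_grammar()
  S <- spec$image_size
  with_local_seed(phantom_sample_seed(spec$seed, index), function() {
    kinds <- setdiff(spec$catalogue, "none")
    kmax <- min(spec$max_pathologies, length(kinds))
    n_les <- if (kmax == 0 || !length(kinds)) 0L else {
      probs <- c(0.3, 0.5, 0.2)[seq_len(kmax + 1L)]
      sample(0:kmax, 1L, prob = probs / sum(probs))
    }
    labels <- if (n_les == 0L) "none" else
      sort(sample(kinds, n_les))
    img <- phantom_template(S)
    masks <- list()
    sentences <- character(0)
    keywords <- character(0)
    for (kind in setdiff(labels, "none")) {
      les <- phantom_lesion(kind, S)
      img <- img + les$add
      masks[[kind]] <- les$mask
      vs <- gr[[kind]]$variants
      sentences <- c(sentences, vs[sample.int(length(vs), 1L)])
      keywords <- c(keywords, gr[[kind]]$keyword)
    }
    if (identical(labels, "none")) {
      sentences <- gr$none$variants
      keywords <- gr$none$keyword
    }
    if (spec$noise_sigma > 0 && noise) {
      img <- img + matrix(stats::rnorm(S * S, 0, spec$noise_sigma), S, S)
    }
    img <- pmin(pmax(img, 0), 1)
    phrases <- vapply(labels, function(k) gr[[k]]$phrase, "")
    impression <- paste0(paste(phrases, collapse = " and "), ".")
    findings <- paste0(paste(sentences, collapse = ". "), ".")
    body <- assemble_report(impression, findings)
    report <- prepend_labels(label_token(labels), body)
    structure(list(image = img, report = report,
                   impression = impression, findings = findings,
                   labels = labels, masks = masks, keywords = keywords,
                   sample_id = sprintf("phantom_%06d", index)),
              class = "phantom_sample")
  })
}

#' Canonical label token for a pathology kind
#'
#' Label tokens are the catalogue names stripped of non-alphanumeric
#' characters, so they survive text normalization as single tokens.
#'
#' @param kind Character vector of pathology kinds.
#' @return Character vector of tokens.
#' @export
label_token <- function(kind) gsub("[^a-z0-9]", "", tolower(kind))

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample>", x$sample_id, "\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  cat("  report:", x$report, "\n")
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes images to an HDF5 store (dataset `images`, shape
#' `(n, 1, size, size)` in C order, float32, values in \[0,1\]), the reports
#' to a JSON-lines file with fields `sample_id`, `impression`, `findings`,
#' `labels`, and a manifest listing sample ids in order.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of samples (> 0).
#' @param out_image_store Path of the HDF5 file to create.
#' @param out_reports Path of the JSON-lines report file.
#' @param out_manifest Optional path for a plain-text manifest (one id per
#'   line); omitted when `NULL`.
#' @return A tibble manifest with `sample_id`, `labels` (list-column) and
#'   `index`, invisibly used by downstream stages.
#' @export
generate_dataset <- function(spec, n, out_image_store, out_reports,
                             out_manifest = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n <= 0) stop("n must be > 0")
  S <- spec$image_size
  if (file.exists(out_image_store)) unlink(out_image_store)
  ok <- rhdf5::h5createFile(out_image_store)
  if (!isTRUE(ok)) stop("cannot create image store at ", out_image_store)
  rhdf5::h5createDataset(out_image_store, "images",
                         dims = c(S, S, 1L, n),
                         chunk = c(S, S, 1L, min(n, 16L)),
                         H5type = "H5T_IEEE_F32LE")
  con <- file(out_reports, open = "wb")
  on.exit(close(con), add = TRUE)
  ids <- character(n)
  labsets <- vector("list", n)
  chunk <- 16L
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    block <- array(0, dim = c(S, S, 1L, end - start + 1L))
    for (i in start:end) {
      s <- generate_phantom(spec, i - 1L)
      # store transposed so C-order readers see [i, 0, row, col]
      block[, , 1L, i - start + 1L] <- t(s$image)
      ids[i] <- s$sample_id
      labsets[[i]] <- s$labels
      line <- jsonlite::toJSON(list(sample_id = s$sample_id,
                                    impression = s$impression,
                                    findings = s$findings,
                                    labels = s$labels),
                               auto_unbox = TRUE)
      writeLines(as.character(line), con, sep = "\n")
    }
    rhdf5::h5write(block, out_image_store, "images",
                   index = list(NULL, NULL, NULL, start:end))
  }
  rhdf5::h5closeAll()
  if (!is.null(out_manifest)) writeLines(ids, out_manifest)
  tibble::tibble(sample_id = ids, labels = labsets,
                 index = seq_len(n) - 1L)
}

#' Read images back from an HDF5 store
#'
#' @param path HDF5 file written by [generate_dataset()].
#' @param indices 1-based sample indices; `NULL` reads all.
#' @return Array of shape `(size, size, n)` with images in row/column
#'   orientation matching [generate_phantom()].
#' @export
read_image_store <- function(path, indices = NULL) {
  if (!file.exists(path)) stop("image store not found: ", path)
  idx <- if (is.null(idx <- indices)) NULL else list(NULL, NULL, NULL, idx)
  x <- rhdf5::h5read(path, "images", index = idx)
  rhdf5::h5closeAll()
  n <- dim(x)[4]
  out <- array(0, dim = c(dim(x)[2], dim(x)[1], n))
  for (i in seq_len(n)) out[, , i] <- t(x[, , 1L, i])
  out
}

#' Read a JSON-lines report file
#'
#' @param path JSON-lines file from [generate_dataset()].
#' @return Tibble with `sample_id`, `impression`, `findings`, `labels`
#'   (list-column).
#' @export
read_reports <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    sample_id = vapply(recs, `[[`, "", "sample_id"),
    impression = vapply(recs, `[[`, "", "impression"),
    findings = vapply(recs, `[[`, "", "findings"),
    labels = lapply(recs, function(r) as.character(r$labels))
  )
}

#' Split sample ids into train/validation/test partitions
#'
#' Deterministic shuffle followed by a largest-remainder allocation, so the
#' three lists always partition the input exactly.
#'
#' @param ids Character vector of sample ids (or a manifest tibble with a
#'   `sample_id` column).
#' @param fractions Numeric length-3 vector summing to 1.  The default
#'   allocates 75\% to training, 24.75\% to validation and 0.25\% to testing.
#' @param seed Integer seed for the shuffle.
#' @return List with `train`, `val`, `test` character vectors.
#' @export
#' @examples
#' sp <- split_dataset(sprintf("s%04d", 1:10000), seed = 1)
#' lengths(sp)  # 7500 2475 25
split_dataset <- function(ids, fractions = c(0.75, 0.2475, 0.0025),
                          seed = 1L) {
  if (is.data.frame(ids)) ids <- ids$sample_id
  if (length(fractions) != 3L || any(fractions < 0)) {
    stop("fractions must be three non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- length(ids)
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  perm <- with_local_seed(seed, function() sample.int(n))
  shuffled <- ids[perm]
  ends <- cumsum(sizes)
  list(train = shuffled[seq_len(sizes[1])],
       val = if (sizes[2] > 0) shuffled[(ends[1] + 1):ends[2]]
             else character(0),
       test = if (sizes[3] > 0) shuffled[(ends[2] + 1):ends[3]]
              else character(0))
}
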