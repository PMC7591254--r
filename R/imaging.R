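#' Render a synthetic immunofluorescence field with ground truth
#'
#' Places non-overlapping disk-shaped cells of given phenotypes in a field
#' and renders one intensity image per channel, with optional Gaussian
#' noise. Each phenotype specifies how many cells to draw and the intensity
#' it shows in each channel (e.g. an IBA1+MAC2+ cell is bright in both the
#' IBA1 and MAC2 channels); a channel absent from a phenotype's intensity
#' map renders as background for those cells. The returned ground truth
#' records every cell's phenotype and footprint, so segmentation and
#' colocalization can be scored exactly.
#'
#' @param phenotypes named list; each element is
#'   `list(n = <cells>, channels = c(IBA1 = 180, MAC2 = 150, ...))`.
#' @param width,height field size in pixels.
#' @param radius cell radius in pixels (scalar or per-phenotype).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param pixel_size microns per pixel (metadata only).
#' @param seed RNG seed.
#' @param max_tries placement attempts per cell before declaring the field
#'   too dense (error).
#' @return List of class `channel_stack`: `channels` (named list of
#'   height x width matrices), `truth` (data.frame: id, phenotype, x, y,
#'   radius plus one `<channel>_pos` flag per channel), `pixel_size`.
#' @export
synth_image <- function(phenotypes, width = 512, height = 512, radius = 6,
                        noise_sd = 0, pixel_size = 1, seed = 1L,
                        max_tries = 2000) {
  channels <- unique(unlist(lapply(phenotypes, function(p) {
    names(p$channels)
  })))
  n_total <- sum(vapply(phenotypes, function(p) p$n, numeric(1)))
  radii <- rep_len(radius, length(phenotypes))
  imgs <- setNames(lapply(channels, function(ch) {
    matrix(0, height, width)
  }), channels)
  truth <- NULL
  with_seed(seed, {
    xs <- ys <- rs <- numeric(0)
    rows <- list()
    id <- 0
    for (k in seq_along(phenotypes)) {
      ph <- phenotypes[[k]]
      r <- radii[k]
      if ((ph$n %||% 0) == 0) next
      for (i in seq_len(ph$n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          x <- runif(1, r + 1, width - r)
          y <- runif(1, r + 1, height - r)
          if (length(xs) == 0 ||
              all((xs - x)^2 + (ys - y)^2 > (rs + r + 3)^2)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("field too dense: could not place cell ", id + 1, " of ",
               n_total)
        }
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
        id <- id + 1
        # disk footprint
        cols <- max(1, floor(x - r)):min(width, ceiling(x + r))
        rws <- max(1, floor(y - r)):min(height, ceiling(y + r))
        dist2 <- outer((rws - y)^2, (cols - x)^2, `+`)
        inside <- dist2 <= r^2
        for (ch in names(ph$channels)) {
          sub <- imgs[[ch]][rws, cols]
          sub[inside] <- ph$channels[[ch]]
          imgs[[ch]][rws, cols] <- sub
        }
        pos <- setNames(channels %in% names(ph$channels), channels)
        rows[[id]] <- data.frame(id = id, phenotype = names(phenotypes)[k],
                                 x = x, y = y, radius = r,
                                 t(as.data.frame(pos)), check.names = FALSE)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(id = integer(0), phenotype = character(0),
                 x = numeric(0), y = numeric(0), radius = numeric(0))
    }
    if (noise_sd > 0) {
      for (ch in channels) {
        imgs[[ch]] <- pmax(imgs[[ch]] +
                             matrix(rnorm(height * width, 0, noise_sd),
                                    height, width), 0)
      }
    }
  })
  if (length(truth$id)) {
    names(truth) <- sub("^(.*)\\.pos$", "\\1", names(truth))
    colnames(truth)[-(1:5)] <- paste0(channels, "_pos")
    rownames(truth) <- NULL
  }
  structure(list(channels = imgs, truth = truth, pixel_size = pixel_size),
            class = "channel_stack")
}

#' Adaptive (local-mean) threshold segmentation mask
#'
#' Marks a pixel as foreground when its intensity strictly exceeds the mean
#' intensity of the surrounding `window` x `window` neighbourhood plus
#' `offset`. Borders are handled by edge replication. This is the
#' local-threshold rule used to segment unevenly illuminated
#' immunofluorescence channels.
#'
#' @param image numeric matrix of intensities.
#' @param window odd window side length in pixels, >= 3.
#' @param offset intensity added to the local mean before comparison.
#' @return Logical matrix, same shape.
#' @export
adaptive_threshold <- function(image, window = 51, offset = 0) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  nr <- nrow(image); nc <- ncol(image)
  if (window > nr || window > nc) {
    stop("window (", window, ") larger than image (", nr, "x", nc, ")")
  }
  h <- (window - 1) / 2
  ri <- pmin(pmax(seq_len(nr + 2 * h) - h, 1), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * h) - h, 1), nc)
  padded <- image[ri, ci]
  # integral image with a zero top row / left column
  S <- matrix(0, nr + 2 * h + 1, nc + 2 * h + 1)
  S[-1, -1] <- apply(apply(padded, 2, cumsum), 1, cumsum) |> t()
  r2 <- (seq_len(nr)) + 2 * h; r1 <- seq_len(nr)
  c2 <- (seq_len(nc)) + 2 * h; c1 <- seq_len(nc)
  box <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  local_mean <- box / window^2
  image > local_mean + offset
}

#' Label connected components of a binary mask
#'
#' 8-connected component labelling; components smaller than `min_size`
#' pixels are discarded and the survivors renumbered 1..n in raster order
#' of their first pixel, so labels are deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_size minimum object area in pixels (default 30).
#' @return A `label_image`: list with `labels` (integer matrix, 0 =
#'   background) and `objects` (data.frame: label, area, centroid cx, cy
#'   in pixel coordinates, x = column, y = row).
#' @export
segment_mask <- function(mask, min_size = 30) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx)) {
    pos <- match(seq_len(nr * nc), idx) # pixel -> vertex id
    edge_to <- function(dr, dc) {
      r <- (idx - 1) %% nr + 1
      c <- (idx - 1) %/% nr + 1
      ok <- r + dr >= 1 & r + dr <= nr & c + dc >= 1 & c + dc <= nc
      nb <- idx[ok] + dr + dc * nr
      ok2 <- mask[nb]
      cbind(pos[idx[ok][ok2]], pos[nb[ok2]])
    }
    edges <- rbind(edge_to(1, 0), edge_to(0, 1), edge_to(1, 1),
                   edge_to(-1, 1))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    # renumber by raster order of first pixel, drop small components
    first <- tapply(seq_along(idx), memb, min)
    ord <- order(first)
    relab <- integer(length(ord)); relab[ord] <- seq_along(ord)
    memb <- relab[memb]
    area <- tabulate(memb)
    keep <- which(area >= min_size)
    final <- integer(length(area)); final[keep] <- seq_along(keep)
    lab <- final[memb]
    labels[idx] <- lab
  }
  objs <- which(labels > 0)
  if (length(objs)) {
    lab <- labels[objs]
    r <- (objs - 1) %% nr + 1
    c <- (objs - 1) %/% nr + 1
    objects <- data.frame(label = sort(unique(lab)),
                          area = as.numeric(tabulate(lab)[sort(unique(lab))]),
                          cx = as.numeric(tapply(c, lab, mean)),
                          cy = as.numeric(tapply(r, lab, mean)),
                          row.names = NULL)
  } else {
    objects <- data.frame(label = integer(0), area = numeric(0),
                          cx = numeric(0), cy = numeric(0))
  }
  structure(list(labels = labels, objects = objects), class = "label_image")
}

#' Colocalize objects between two segmented channels
#'
#' Pairs object `i` of channel A with object `j` of channel B when their
#' pixel overlap, divided by the smaller of the two object areas, strictly
#' exceeds `min_overlap` (default 10%; an exact-10% overlap is not
#' paired). Each object joins at most one pair: candidate pairs are
#' accepted in decreasing overlap order (ties: lower labels first), so
#' dense fields are not double-counted. The min-area denominator makes the
#' rule symmetric in the two channels.
#'
#' @param a,b `label_image`s of the same shape.
#' @param min_overlap overlap fraction that must be exceeded (default 0.10).
#' @return data.frame with label_a, label_b, overlap_px, overlap_frac.
#' @export
colocalize <- function(a, b, min_overlap = 0.10) {
  stopifnot(is(a, "label_image"), is(b, "label_image"))
  if (!all(dim(a$labels) == dim(b$labels))) stop("shape mismatch")
  both <- a$labels > 0 & b$labels > 0
  empty <- data.frame(label_a = integer(0), label_b = integer(0),
                      overlap_px = numeric(0), overlap_frac = numeric(0))
  if (!any(both)) return(empty)
  la <- a$labels[both]; lb <- b$labels[both]
  key <- paste(la, lb)
  cnt <- table(key)
  pairs <- do.call(rbind, strsplit(names(cnt), " "))
  df <- data.frame(label_a = as.integer(pairs[, 1]),
                   label_b = as.integer(pairs[, 2]),
                   overlap_px = as.numeric(cnt))
  area_a <- a$objects$area[match(df$label_a, a$objects$label)]
  area_b <- b$objects$area[match(df$label_b, b$objects$label)]
  df$overlap_frac <- df$overlap_px / pmin(area_a, area_b)
  df <- df[df$overlap_frac > min_overlap, , drop = FALSE]
  if (nrow(df) == 0) return(empty)
  df <- df[order(-df$overlap_px, df$label_a, df$label_b), , drop = FALSE]
  used_a <- used_b <- integer(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!(df$label_a[i] %in% used_a) && !(df$label_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, df$label_a[i])
      used_b <- c(used_b, df$label_b[i])
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify anchor-channel objects by marker colocalization
#'
#' Takes segmented label images per channel and classifies every object of
#' the anchor channel (IBA1, the pan-microglial marker) by which other
#' markers colocalize with it under the >10% overlap rule, e.g. into
#' IBA1+MAC2+ vs IBA1+MAC2-. Phenotype counts partition the anchor
#' objects.
#'
#' @param channel_labels named list of `label_image`s; must contain
#'   `anchor`.
#' @param anchor anchor channel name (default `"IBA1"`).
#' @param min_overlap overlap fraction for [colocalize()].
#' @return List of class `phenotype_counts`: `n_anchor`; `positive`
#'   (anchor-objects x markers logical matrix); `counts` (named vector,
#'   one entry per marker combination such as `"IBA1+MAC2+"`);
#'   `fractions` (per marker, percentage of anchor objects positive).
#' @export
count_phenotypes <- function(channel_labels, anchor = "IBA1",
                             min_overlap = 0.10) {
  if (!anchor %in% names(channel_labels)) {
    stop("anchor channel '", anchor, "' missing")
  }
  anc <- channel_labels[[anchor]]
  markers <- setdiff(names(channel_labels), anchor)
  n_anchor <- nrow(anc$objects)
  positive <- matrix(FALSE, n_anchor, length(markers),
                     dimnames = list(anc$objects$label, markers))
  for (m in markers) {
    pairs <- colocalize(anc, channel_labels[[m]], min_overlap)
    positive[match(pairs$label_a, anc$objects$label), m] <- TRUE
  }
  combo <- apply(positive, 1, function(p) {
    paste0(anchor, "+", paste0(markers, ifelse(p, "+", "-"),
                               collapse = ""))
  })
  all_combos <- apply(expand.grid(rep(list(c("+", "-")), length(markers))),
                      1, function(s) {
                        paste0(anchor, "+",
                               paste0(markers, s, collapse = ""))
                      })
  counts <- setNames(vapply(all_combos, function(cb) sum(combo == cb),
                            numeric(1)), all_combos)
  fractions <- setNames(vapply(markers, function(m) {
    if (n_anchor == 0) 0 else 100 * sum(positive[, m]) / n_anchor
  }, numeric(1)), markers)
  structure(list(n_anchor = n_anchor, positive = positive, counts = counts,
                 fractions = fractions, anchor = anchor),
            class = "phenotype_counts")
}

#' Marker-positive fraction within a phenotype subset
#'
#' Percentage of anchor objects positive for `marker`, optionally
#' restricted to objects matching `within` (e.g. the EdU+ fraction of
#' IBA1+MAC2+ cells via `marker = "EdU"`, `within = c(MAC2 = TRUE)`).
#'
#' @param pc a `phenotype_counts`.
#' @param marker marker column to score.
#' @param within optional named logical vector of marker constraints.
#' @return Percentage (0-100), `NA` when the subset is empty.
#' @export
phenotype_fraction <- function(pc, marker, within = NULL) {
  sel <- rep(TRUE, pc$n_anchor)
  for (m in names(within)) sel <- sel & (pc$positive[, m] == within[[m]])
  if (!any(sel)) return(NA_real_)
  100 * sum(pc$positive[sel, marker]) / sum(sel)
}

#' Mean intensity of a channel over each anchor object
#'
#' @param intensity_channel numeric intensity matrix.
#' @param anchor a `label_image` of the same shape.
#' @return data.frame with label, area, mean_intensity; the per-image
#'   summary (mean over objects) is attribute `image_mean`.
#' @export
mean_intensity_per_object <- function(intensity_channel, anchor) {
  stopifnot(is(anchor, "label_image"))
  if (!all(dim(intensity_channel) == dim(anchor$labels))) {
    stop("shape mismatch")
  }
  if (nrow(anchor$objects) == 0) {
    out <- data.frame(label = integer(0), area = numeric(0),
                      mean_intensity = numeric(0))
    attr(out, "image_mean") <- NA_real_
    return(out)
  }
  fg <- anchor$labels > 0
  m <- tapply(intensity_channel[fg], anchor$labels[fg], mean)
  out <- data.frame(label = as.integer(names(m)),
                    area = anchor$objects$area[
                      match(as.integer(names(m)), anchor$objects$label)],
                    mean_intensity = as.numeric(m), row.names = NULL)
  attr(out, "image_mean") <- mean(out$mean_intensity)
  out
}

#' Read / write intensity and label images as TIFF
#'
#' Intensities are stored as 16-bit TIFF on a 0-65535 scale.
#'
#' @param image numeric matrix (intensities in [0, 65535]) or a
#'   `label_image`.
#' @param path TIFF file path.
#' @export
write_image_tiff <- function(image, path) {
  if (is(image, "label_image")) image <- image$labels
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535, 6)
}
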