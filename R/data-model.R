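#' Build a genotype table
#'
#' The central data structure of the package is the *genotype table*: a long
#' tibble with one row per individual-by-locus genotype and columns
#' `individual_id`, `colony_id`, `locus`, `allele_1`, `allele_2`. Alleles are
#' opaque integer codes (nominally fragment sizes in base pairs); a missing
#' genotype has `NA` in both allele columns. Genotypes are stored unordered
#' and canonicalised so that `allele_1 <= allele_2`.
#'
#' @param x A data frame with columns `individual_id`, `colony_id`, `locus`,
#'   `allele_1`, `allele_2`.
#' @param loci Optional character vector fixing the locus order. Defaults to
#'   order of first appearance.
#' @return A tibble of class `gen_tbl` with a `loci` attribute.
#' @export
gen_tbl <- function(x, loci = NULL) {
  required <- c("individual_id", "colony_id", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  x$individual_id <- as.character(x$individual_id)
  x$colony_id <- as.character(x$colony_id)
  x$locus <- as.character(x$locus)
  x$allele_1 <- as.integer(x$allele_1)
  x$allele_2 <- as.integer(x$allele_2)
  # one NA allele implies the whole genotype is treated as missing
  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    x$allele_1[half] <- NA_integer_
    x$allele_2[half] <- NA_integer_
  }
  swap <- !is.na(x$allele_1) & x$allele_1 > x$allele_2
  tmp <- x$allele_1[swap]
  x$allele_1[swap] <- x$allele_2[swap]
  x$allele_2[swap] <- tmp
  if (is.null(loci)) loci <- unique(x$locus)
  if (!all(x$locus %in% loci)) stop("locus values outside the declared locus list")
  x$locus <- factor(x$locus, levels = loci)
  x <- dplyr::arrange(x, match(.data$colony_id, unique(x$colony_id)),
                      .data$individual_id, .data$locus)
  x$locus <- as.character(x$locus)
  attr(x, "loci") <- loci
  class(x) <- c("gen_tbl", class(x))
  x
}

#' Locus order of a genotype table
#' @param gt A genotype table.
#' @return Character vector of locus names in file order.
#' @export
loci_of <- function(gt) {
  lv <- attr(gt, "loci")
  if (is.null(lv)) lv <- unique(gt$locus)
  lv
}

#' Read a GENEPOP file
#'
#' Parses the classic GENEPOP dialect: a title line, locus names (one per
#' line or comma-separated), `pop` separators, and genotype rows of the form
#' `id , 092105 ...` with 2- or 3-digit per-allele codes. Allele code 0
#' (`00`/`000`) marks a missing allele; a genotype with any missing allele is
#' treated as wholly missing. Each `pop` block becomes one colony; the colony
#' id is the shared row label when all rows of a block share one, otherwise
#' `pop_<k>`.
#'
#' @param path Path to a GENEPOP text file.
#' @return A [gen_tbl()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GENEPOP file too short: ", path)
  lines <- sub("﻿", "", lines)
  is_pop <- function(s) tolower(trimws(s)) == "pop"
  body <- lines[-1]
  first_pop <- which(vapply(body, is_pop, logical(1)))[1]
  if (is.na(first_pop)) stop("no 'pop' separator found in ", path)
  locus_lines <- trimws(body[seq_len(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("no locus names found in ", path)
  if (anyDuplicated(loci)) stop("duplicated locus names in ", path)

  rows <- list()
  pop_idx <- 0L
  pop_labels <- character(0)
  cur_labels <- character(0)
  cur_rows <- list()
  flush_pop <- function() {
    if (pop_idx == 0L) return(invisible(NULL))
    lab <- if (length(unique(cur_labels)) == 1 && nzchar(cur_labels[1])) {
      cur_labels[1]
    } else {
      paste0("pop_", pop_idx)
    }
    if (lab %in% pop_labels) lab <- paste0(lab, "_", pop_idx)
    for (k in seq_along(cur_rows)) {
      cur_rows[[k]]$colony_id <- lab
      cur_rows[[k]]$individual_id <- paste0(lab, "_w", k)
    }
    rows[[length(rows) + 1L]] <<- cur_rows
    pop_labels[pop_idx] <<- lab
    invisible(NULL)
  }
  for (ln in seq(first_pop, length(body))) {
    raw <- body[ln]
    if (!nzchar(trimws(raw))) next
    if (is_pop(raw)) {
      flush_pop()
      pop_idx <- pop_idx + 1L
      cur_labels <- character(0)
      cur_rows <- list()
      next
    }
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      stop("line ", ln + 1L, ": genotype row lacks the 'id ,' separator")
    }
    label <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != length(loci)) {
      stop("line ", ln + 1L, ": ", length(fields), " genotype fields for ",
           length(loci), " loci")
    }
    widths <- nchar(fields)
    if (!all(widths %in% c(4L, 6L)) || length(unique(widths)) != 1L ||
        !all(grepl("^[0-9]+$", fields))) {
      stop("line ", ln + 1L, ": malformed allele field width (need uniform ",
           "4- or 6-digit diploid fields)")
    }
    w <- widths[1] / 2L
    a1 <- as.integer(substr(fields, 1L, w))
    a2 <- as.integer(substr(fields, w + 1L, 2L * w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    cur_labels <- c(cur_labels, label)
    cur_rows[[length(cur_rows) + 1L]] <- tibble::tibble(
      individual_id = NA_character_, colony_id = NA_character_,
      locus = loci, allele_1 = a1, allele_2 = a2)
  }
  flush_pop()
  if (length(rows) == 0) stop("no genotype rows found in ", path)
  gen_tbl(dplyr::bind_rows(unlist(rows, recursive = FALSE)), loci = loci)
}

#' Write a GENEPOP file
#'
#' Emits the 3-digit dialect; missing genotypes become `000000`. Row labels
#' are the colony ids, so a read/write round trip preserves the colony
#' partition, locus order and genotype content.
#'
#' @param gt A genotype table.
#' @param path Output file path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, title = "colonystruct export") {
  loci <- loci_of(gt)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(gt, field = ifelse(
      is.na(.data$allele_1), "000000",
      sprintf("%03d%03d", .data$allele_1, .data$allele_2))),
    id_cols = c("individual_id", "colony_id"),
    names_from = "locus", values_from = "field")
  out <- c(title, loci)
  for (col in unique(wide$colony_id)) {
    out <- c(out, "pop")
    block <- wide[wide$colony_id == col, loci, drop = FALSE]
    out <- c(out, paste0(col, " , ", apply(block, 1, paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a colony metadata table
#'
#' CSV with header `colony_id,x,y[,haplotype]`; coordinates are planar
#' meters, the haplotype column (mtDNA label such as `HT1`) is optional and
#' may contain empty cells.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `colony_id`, `x`, `y`, `haplotype`.
#' @export
read_colony_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("colony table needs columns colony_id, x, y")
  }
  df$colony_id <- as.character(df$colony_id)
  if (anyDuplicated(df$colony_id)) stop("duplicate colony id in ", path)
  for (v in c("x", "y")) {
    val <- suppressWarnings(as.numeric(df[[v]]))
    if (anyNA(val) || any(!is.finite(val))) stop("non-numeric coordinate in column ", v)
    df[[v]] <- val
  }
  if (!"haplotype" %in% names(df)) df$haplotype <- NA_character_
  df$haplotype <- as.character(df$haplotype)
  df$haplotype[!is.na(df$haplotype) & !nzchar(trimws(df$haplotype))] <- NA_character_
  tibble::as_tibble(df[, c("colony_id", "x", "y", "haplotype")])
}

#' Write a colony metadata table
#' @param geo Tibble with columns `colony_id`, `x`, `y` and optionally `haplotype`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(geo, path) {
  out <- as.data.frame(geo)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Project longitude/latitude to planar meters
#'
#' Equirectangular projection at the mean latitude, a convention adequate at
#' the few-hundred-kilometre scale where Euclidean distances are wanted.
#'
#' @param geo Tibble with columns `colony_id`, `x` (longitude, degrees) and
#'   `y` (latitude, degrees).
#' @return The tibble with `x`, `y` replaced by planar meters (origin at the
#'   centroid).
#' @export
project_lonlat <- function(geo) {
  r_earth <- 6371000
  lat0 <- mean(geo$y) * pi / 180
  geo$x <- (geo$x - mean(geo$x)) * pi / 180 * r_earth * cos(lat0)
  geo$y <- (geo$y - mean(geo$y)) * pi / 180 * r_earth
  geo
}

#' Per-group allele frequencies
#'
#' Frequencies are computed over non-missing gene copies. Groups with zero
#' copies at a locus are retained with `n_copies = 0` and `NA` frequency so
#' downstream code can drop or flag them.
#'
#' @param gt A genotype table.
#' @param group Either `"colony"` (default; one group per colony) or a data
#'   frame `colony_id`/`group` mapping colonies to groups.
#' @return A tibble `group`, `locus`, `allele`, `count`, `n_copies`, `freq`.
#' @export
allele_frequencies <- function(gt, group = "colony") {
  gt <- dplyr::mutate(gt, .group = .group_of(gt, group))
  long <- tidyr::pivot_longer(gt, c("allele_1", "allele_2"),
                              values_to = "allele")
  long <- dplyr::filter(long, !is.na(.data$allele))
  counts <- dplyr::count(long, .data$.group, .data$locus, .data$allele,
                         name = "count")
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$.group, .data$locus),
    n_copies = sum(.data$count), freq = .data$count / .data$n_copies)
  counts <- dplyr::ungroup(counts)
  # groups with zero copies at a locus: reinstate explicitly
  all_groups <- unique(gt$.group)
  frame <- tidyr::expand_grid(.group = all_groups, locus = loci_of(gt))
  have <- dplyr::distinct(counts, .data$.group, .data$locus)
  gone <- dplyr::anti_join(frame, have, by = c(".group", "locus"))
  if (nrow(gone) > 0) {
    gone <- dplyr::mutate(gone, allele = NA_integer_, count = 0L,
                          n_copies = 0L, freq = NA_real_)
    counts <- dplyr::bind_rows(counts, gone)
  }
  out <- dplyr::rename(counts, group = ".group")
  dplyr::arrange(out, match(.data$group, all_groups),
                 match(.data$locus, loci_of(gt)), .data$allele)
}

#' Per-colony allele frequencies
#' @param gt A genotype table.
#' @return A tibble as [allele_frequencies()] with one group per colony.
#' @export
colony_allele_frequencies <- function(gt) allele_frequencies(gt, "colony")

# internal: resolve a grouping spec to one group label per row of gt
.group_of <- function(gt, group) {
  if (is.character(group) && length(group) == 1 && group == "colony") {
    return(gt$colony_id)
  }
  if (is.data.frame(group)) {
    m <- setNames(as.character(group$group), group$colony_id)
    out <- m[gt$colony_id]
    if (anyNA(out)) stop("grouping table misses some colonies")
    return(unname(out))
  }
  if (!is.null(names(group))) {
    out <- as.character(group[gt$colony_id])
    if (anyNA(out)) stop("grouping vector misses some colonies")
    return(out)
  }
  stop("unsupported group specification")
}

#' Frequency matrix (groups x alleles)
#'
#' Reshapes the long frequency tibble into a numeric matrix with one row per
#' group and one column per `locus.allele` combination (e.g. `loc1.228`),
#' the input shape used by the spatial PCA and Edwards' distance. Zero-copy
#' cells become `NA`.
#'
#' @param freqs Output of [allele_frequencies()].
#' @return A numeric matrix with rownames = groups.
#' @export
freq_matrix <- function(freqs) {
  freqs <- dplyr::filter(freqs, !is.na(.data$allele))
  freqs <- dplyr::mutate(freqs, key = paste0(.data$locus, ".", .data$allele))
  keys <- unique(freqs$key)
  groups <- unique(freqs$group)
  m <- matrix(0, nrow = length(groups), ncol = length(keys),
              dimnames = list(groups, keys))
  m[cbind(match(freqs$group, groups), match(freqs$key, keys))] <- freqs$freq
  # a group with zero copies at a locus gets NA across that locus's columns
  zero <- dplyr::distinct(
    dplyr::filter(dplyr::group_by(freqs, .data$group, .data$locus),
                  sum(.data$n_copies) == 0),
    .data$group, .data$locus)
  if (nrow(zero) > 0) {
    for (i in seq_len(nrow(zero))) {
      cols <- startsWith(keys, paste0(zero$locus[i], "."))
      m[zero$group[i], cols] <- NA_real_
    }
  }
  m
}

#' Summarise mtDNA haplotype labels
#'
#' @param geo Colony metadata tibble with a `haplotype` column.
#' @param region Optional vector or `colony_id`/`group` data frame assigning
#'   colonies to regions; when given, per-region summaries are appended.
#' @return A tibble `region`, `haplotype`, `n`, `proportion` (region
#'   `"all"` for the overall summary). Colonies with no label are excluded.
#' @export
haplotype_summary <- function(geo, region = NULL) {
  lab <- dplyr::filter(geo, !is.na(.data$haplotype))
  if (nrow(lab) == 0) {
    return(tibble::tibble(region = character(0), haplotype = character(0),
                          n = integer(0), proportion = numeric(0)))
  }
  one <- function(d, reg) {
    s <- dplyr::count(d, .data$haplotype, name = "n")
    tibble::tibble(region = reg, haplotype = s$haplotype, n = s$n,
                   proportion = s$n / sum(s$n))
  }
  out <- one(lab, "all")
  if (!is.null(region)) {
    if (is.data.frame(region)) {
      region <- setNames(as.character(region$group), region$colony_id)
    }
    lab$region <- region[lab$colony_id]
    for (r in unique(lab$region)) {
      out <- dplyr::bind_rows(out, one(lab[lab$region == r, ], r))
    }
  }
  out
}
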