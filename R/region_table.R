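# Region catalogue: the ordered node set of the covariance network.

# Left-hemisphere AAL cerebral regions (cerebellum excluded), split into the
# 39 neocortical and 6 subcortical structures used as network nodes, plus the
# 8 ascending-arousal-network brainstem nuclei.
.aal_left_neocortical <- c(
  "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
  "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri", "Frontal_Inf_Orb",
  "Rolandic_Oper", "Supp_Motor_Area", "Olfactory", "Frontal_Sup_Medial",
  "Frontal_Med_Orb", "Rectus", "Insula", "Cingulum_Ant", "Cingulum_Mid",
  "Cingulum_Post", "ParaHippocampal", "Calcarine", "Cuneus", "Lingual",
  "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform", "Postcentral",
  "Parietal_Sup", "Parietal_Inf", "SupraMarginal", "Angular", "Precuneus",
  "Paracentral_Lobule", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
  "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")

.aal_left_subcortical <- c(
  "Hippocampus", "Amygdala", "Caudate", "Putamen", "Pallidum", "Thalamus")

.aan_brainstem <- c(
  "Dorsal_Raphe", "Median_Raphe", "Locus_Coeruleus", "Periaqueductal_Gray",
  "Parabrachial_Complex", "Pontis_Oralis", "Pedunculopontine_Nucleus",
  "Ventral_Tegmental_Area")

#' Build the ordered region table of network nodes
#'
#' Creates the node catalogue for a metabolic covariance network: an ordered
#' table of brain regions with anatomical category (neocortical, subcortical,
#' brainstem), hemisphere, a unique integer label matching the parcellation
#' volume, a seed flag (exactly one region, the insula by default), and an
#' appended cerebellar reference region used only for intensity normalization
#' (never a network node).
#'
#' The default composition is 39 neocortical + 6 subcortical + 8 brainstem
#' regions (53 network nodes), named from the left-hemisphere AAL atlas and
#' the Harvard ascending arousal network atlas. Non-default counts receive
#' systematic synthetic names.
#'
#' @param n_neocortical,n_subcortical,n_brainstem Number of regions per
#'   anatomical category; all must be >= 1.
#' @param seed_name Name of the seed region. Matched case-insensitively
#'   against the neocortical names; if absent, the first neocortical region is
#'   renamed to `seed_name`.
#' @param include_reference Append a cerebellar reference region row
#'   (`is_reference = TRUE`)? Default `TRUE`.
#' @return A `data.frame` with columns `region_id`, `name`, `hemisphere`,
#'   `category`, `is_seed`, `is_reference`. Network nodes are the rows with
#'   `is_reference = FALSE`, in table order.
#' @examples
#' tab <- make_region_table()
#' table(tab$category[!tab$is_reference])
#' @export
make_region_table <- function(n_neocortical = 39, n_subcortical = 6,
                              n_brainstem = 8, seed_name = "Insula",
                              include_reference = TRUE) {
  for (v in list(n_neocortical, n_subcortical, n_brainstem)) {
    if (!is_count(v) || v < 1)
      mc_stop("region counts must be positive integers",
              "mcnet_validation_error")
  }
  if (!is.character(seed_name) || length(seed_name) != 1L || !nzchar(seed_name))
    mc_stop("`seed_name` must be a non-empty string", "mcnet_validation_error")

  default_sizes <- n_neocortical == 39 && n_subcortical == 6 && n_brainstem == 8
  if (default_sizes) {
    neo <- .aal_left_neocortical
    sub <- .aal_left_subcortical
    bs  <- .aan_brainstem
  } else {
    neo <- sprintf("Neocortical_%02d", seq_len(n_neocortical))
    sub <- sprintf("Subcortical_%02d", seq_len(n_subcortical))
    bs  <- sprintf("Brainstem_%02d", seq_len(n_brainstem))
  }
  hit <- which(tolower(neo) == tolower(seed_name))
  if (length(hit) == 0L) {
    neo[1L] <- seed_name
    hit <- 1L
  }

  name <- c(neo, sub, bs)
  category <- rep(c("neocortical", "subcortical", "brainstem"),
                  c(n_neocortical, n_subcortical, n_brainstem))
  hemisphere <- ifelse(category == "brainstem", "midline", "left")
  is_seed <- seq_along(name) == hit[1L]
  tab <- data.frame(
    region_id = seq_along(name),
    name = name,
    hemisphere = hemisphere,
    category = category,
    is_seed = is_seed,
    is_reference = FALSE,
    stringsAsFactors = FALSE
  )
  if (include_reference) {
    tab <- rbind(tab, data.frame(
      region_id = nrow(tab) + 1L, name = "Cerebellar_GM",
      hemisphere = "midline", category = "reference",
      is_seed = FALSE, is_reference = TRUE, stringsAsFactors = FALSE))
  }
  validate_region_table(tab)
  tab
}

# Invariant checks shared by the constructor and the TSV reader.
validate_region_table <- function(tab) {
  need <- c("region_id", "name", "hemisphere", "category", "is_seed",
            "is_reference")
  if (!all(need %in% names(tab)))
    mc_stop(paste("region table missing columns:",
                  paste(setdiff(need, names(tab)), collapse = ", ")),
            "mcnet_validation_error")
  if (anyDuplicated(tab$name))
    mc_stop("region names must be unique", "mcnet_validation_error")
  if (anyDuplicated(tab$region_id))
    mc_stop("region ids must be unique", "mcnet_validation_error")
  if (sum(tab$is_seed) != 1L)
    mc_stop("exactly one region must be flagged as seed",
            "mcnet_validation_error")
  if (tab$is_reference[tab$is_seed])
    mc_stop("the seed region cannot be the reference region",
            "mcnet_validation_error")
  invisible(tab)
}

# Network nodes = non-reference rows, in table order.
region_nodes <- function(tab) tab[!tab$is_reference, , drop = FALSE]

#' @rdname make_region_table
#' @param tab A region table.
#' @param path File path for the tab-separated region table.
#' @export
write_region_table <- function(tab, path) {
  validate_region_table(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname make_region_table
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$is_seed <- as.logical(tab$is_seed)
  tab$is_reference <- as.logical(tab$is_reference)
  validate_region_table(tab)
  tab
}
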