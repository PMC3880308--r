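#' Worked example: clothing and footwear hierarchies
#'
#' A small two-hierarchy transaction database for illustrating the
#' hierarchy-aware measures. The first hierarchy is
#' Clothes > Outerwear > {Jackets, Travel Pants}; the second is
#' Footwear > Hiking Boots. The 1000 transactions are constructed so that,
#' after ancestor closure, the item supports are Clothes 150, Outerwear
#' 100, Jackets 90, Travel Pants 15, Hiking Boots 30, and the rules
#' Clothes/Outerwear/Jackets/Travel Pants -> Hiking Boots have absolute
#' supports 30, 20, 15 and 10.
#'
#' The example shows why expectations matter: Jackets -> Hiking Boots has
#' a higher support (15) than Travel Pants -> Hiking Boots (10), but its
#' parent rule Outerwear -> Hiking Boots leads one to expect
#' 20 * 90 / 100 = 18 co-occurrences, more than observed — whereas Travel
#' Pants is expected to yield only 20 * 15 / 100 = 3 and delivers 10. The
#' difference measures rank the second rule higher.
#'
#' @return list with `ontologies` (list of two [ontology()]s) and `store`
#'   (a closed [annotation_store()] of 1000 transactions).
#' @export
toy_clothing_fixture <- function() {
  apparel <- ontology("apparel",
    data.frame(id = c("Clothes", "Outerwear", "Jackets", "Travel Pants"),
               name = c("Clothes", "Outerwear", "Jackets", "Travel Pants"),
               stringsAsFactors = FALSE),
    list("Outerwear" = "Clothes",
         "Jackets" = "Outerwear",
         "Travel Pants" = "Outerwear"))
  footwear <- ontology("footwear",
    data.frame(id = c("Footwear", "Hiking Boots"),
               name = c("Footwear", "Hiking Boots"),
               stringsAsFactors = FALSE),
    list("Hiking Boots" = "Footwear"))

  blocks <- list(
    list(n = 5L,   items = list(apparel = c("Jackets", "Travel Pants"),
                                footwear = "Hiking Boots")),
    list(n = 10L,  items = list(apparel = "Jackets", footwear = "Hiking Boots")),
    list(n = 5L,   items = list(apparel = "Travel Pants", footwear = "Hiking Boots")),
    list(n = 10L,  items = list(apparel = "Clothes", footwear = "Hiking Boots")),
    list(n = 75L,  items = list(apparel = "Jackets")),
    list(n = 5L,   items = list(apparel = "Travel Pants")),
    list(n = 40L,  items = list(apparel = "Clothes")),
    list(n = 850L, items = list(footwear = "Footwear")))

  rows <- list(); obj_id <- 0L
  for (b in blocks) {
    for (i in seq_len(b$n)) {
      obj_id <- obj_id + 1L
      for (ont in names(b$items))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          object_id = sprintf("t%04d", obj_id),
          ontology_id = ont,
          category_id = b$items[[ont]])
    }
  }
  store <- annotation_store(data.table::rbindlist(rows),
                            list(apparel, footwear))
  store <- ancestor_closure(store, list(apparel, footwear))
  list(ontologies = list(apparel, footwear), store = store)
}
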