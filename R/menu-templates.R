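# Per-category text templates and synonym lists for the snapshot simulator.
# Each category has a small set of name and description templates with
# vocabulary that is distinctive for the category (so classifier
# parameter-recovery tests have a separable noise-0 limit), plus synonyms
# used for noisy token substitution.

category_template_list <- function() {
  list(
    "Salad (+ or - dressing or meat)" = list(
      names = c("garden salad", "caesar salad with chicken", "green salad bowl"),
      descs = c("crisp lettuce cucumber and tomato", "fresh leaves with vinaigrette dressing")),
    "Fruit salad or fresh fruit" = list(
      names = c("fresh fruit salad", "seasonal fruit cup", "sliced melon and berries"),
      descs = c("seasonal fruit freshly cut", "ripe fruit pieces no syrup")),
    "Grilled fish and salad" = list(
      names = c("grilled fish with salad", "seared snapper and greens", "grilled salmon salad"),
      descs = c("grilled fillet with leafy greens", "fish char grilled served with salad")),
    "Vegetable soup" = list(
      names = c("vegetable soup", "pumpkin soup", "minestrone soup"),
      descs = c("slow simmered seasonal vegetables", "hearty soup of garden vegetables")),
    "Poke bowl" = list(
      names = c("tuna poke bowl", "salmon poke bowl", "poke bowl with edamame"),
      descs = c("raw fish rice avocado and seaweed", "hawaiian style bowl with pickled ginger")),
    "Sushi roll or bowl" = list(
      names = c("sushi roll set", "salmon nigiri sushi", "teriyaki sushi bowl"),
      descs = c("rice rolls with nori and wasabi", "assorted sushi with soy sauce")),
    "Stir fry with rice" = list(
      names = c("chicken stir fry", "beef stir fry with rice", "wok tossed vegetable stir fry"),
      descs = c("wok fried with jasmine rice", "stir fried vegetables in light sauce")),
    "Wrap or kebab" = list(
      names = c("chicken wrap", "lamb kebab", "falafel wrap"),
      descs = c("warm flatbread with hummus and salad", "kebab meat with garlic yoghurt")),
    "Sandwich - fresh filled" = list(
      names = c("club sandwich", "ham and salad sandwich", "chicken avocado sandwich"),
      descs = c("fresh filled on grain bread", "sandwich with lettuce and mayo")),
    "Noodle soup (pho or ramen)" = list(
      names = c("beef pho", "tonkotsu ramen", "chicken noodle soup"),
      descs = c("rice noodles in fragrant broth", "ramen noodles with soft egg")),
    "Rice meal with vegetables" = list(
      names = c("teriyaki chicken on rice", "bibimbap rice bowl", "nasi goreng"),
      descs = c("steamed rice with seasonal vegetables", "rice bowl topped with greens")),
    "Smoothie" = list(
      names = c("banana smoothie", "mixed berry smoothie", "mango smoothie"),
      descs = c("blended fruit with yoghurt", "smoothie made on milk")),
    "Burger only - premium" = list(
      names = c("wagyu beef burger", "angus burger deluxe", "gourmet chicken burger"),
      descs = c("premium patty brioche bun aioli", "gourmet burger with cheese and bacon")),
    "Pasta - creamy or cheesy" = list(
      names = c("fettuccine carbonara", "mac and cheese", "creamy chicken penne"),
      descs = c("pasta in rich cream sauce", "baked pasta with three cheeses")),
    "Roast meat meal" = list(
      names = c("roast lamb dinner", "roast pork with gravy", "rotisserie chicken meal"),
      descs = c("roast meat with potatoes and gravy", "slow roasted with seasonal sides")),
    "Burrito or loaded taco" = list(
      names = c("beef burrito", "loaded chicken tacos", "pulled pork burrito bowl"),
      descs = c("tortilla with beans cheese and salsa", "loaded with sour cream and guacamole")),
    "Curry with rice" = list(
      names = c("butter chicken curry", "lamb rogan josh", "green thai curry"),
      descs = c("rich curry served with basmati rice", "curry with naan and rice")),
    "Coffee - milk based" = list(
      names = c("flat white", "large latte", "cappuccino"),
      descs = c("espresso with steamed milk", "double shot coffee with milk")),
    "Fruit juice" = list(
      names = c("orange juice", "apple juice", "feijoa juice"),
      descs = c("cold pressed fruit juice", "juice squeezed fresh")),
    "Fried chicken meal" = list(
      names = c("fried chicken bucket", "crispy chicken tenders meal", "wicked wings combo"),
      descs = c("southern fried chicken with chips", "crispy coated chicken pieces")),
    "Pizza - single" = list(
      names = c("margherita pizza", "pepperoni pizza", "hawaiian pizza"),
      descs = c("stone baked with mozzarella", "classic pizza on tomato base")),
    "Kids meal" = list(
      names = c("kids nugget meal", "happy kids combo", "kids cheeseburger meal"),
      descs = c("small meal with toy and drink", "kid sized portion with chips")),
    "Savoury pie or sausage roll" = list(
      names = c("steak and cheese pie", "mince pie", "jumbo sausage roll"),
      descs = c("flaky pastry with savoury filling", "golden baked pie")),
    "Burger only - value" = list(
      names = c("cheeseburger", "value beef burger", "basic chicken burger"),
      descs = c("simple burger with sauce", "value menu burger")),
    "Loaded fries" = list(
      names = c("loaded cheesy fries", "bacon loaded fries", "chilli cheese fries"),
      descs = c("fries smothered in cheese sauce", "topped fries with bacon bits")),
    "Fish and chips" = list(
      names = c("fish and chips", "battered snapper and chips", "fish bites and chips"),
      descs = c("battered fish with hot chips", "classic takeaway fish and chips")),
    "Pizza meal deal" = list(
      names = c("two pizza meal deal", "pizza combo with sides", "family pizza deal"),
      descs = c("pizzas plus garlic bread and soft drink", "meal deal feeds the family")),
    "Alcoholic drink" = list(
      names = c("craft beer six pack", "sauvignon blanc bottle", "vodka premix cans"),
      descs = c("contains alcohol 18 plus only", "chilled alcoholic beverage")),
    "Sugary soft drink" = list(
      names = c("cola 1.5l", "lemonade bottle", "raspberry fizzy drink"),
      descs = c("sweet carbonated soft drink", "sugar sweetened fizzy")),
    "Ice cream or sundae" = list(
      names = c("hot fudge sundae", "vanilla ice cream tub", "choc dipped cone"),
      descs = c("creamy ice cream with topping", "frozen dessert sundae")),
    "Doughnut or sweet pastry" = list(
      names = c("glazed doughnut", "cinnamon doughnut box", "chocolate croissant"),
      descs = c("sweet fried dough with glaze", "flaky pastry dusted with sugar")),
    "Cake or slice" = list(
      names = c("chocolate mud cake", "carrot cake slice", "caramel slice"),
      descs = c("rich baked cake with icing", "sweet slice with frosting")),
    "Confectionery" = list(
      names = c("gummy lolly mix", "chocolate bar", "sour worms bag"),
      descs = c("assorted sweets and lollies", "sugary confectionery treat")),
    "Hot chips only" = list(
      names = c("large hot chips", "curly fries", "kumara fries"),
      descs = c("deep fried golden chips with salt", "crispy fries side")),
    "Milkshake or thickshake" = list(
      names = c("chocolate thickshake", "strawberry milkshake", "caramel shake"),
      descs = c("thick blended shake with syrup", "milkshake topped with cream")),
    "Energy drink" = list(
      names = c("energy drink can", "taurine energy hit", "guarana energy blast"),
      descs = c("high caffeine energy drink", "energy boost beverage"))
  )
}

#' Category text templates for the snapshot simulator
#'
#' @return A tibble with one row per category: `category`, list-columns
#'   `names` and `descs` of template strings.
#' @export
category_templates <- function() {
  tl <- category_template_list()
  tibble(
    category = names(tl),
    names = purrr::map(tl, "names"),
    descs = purrr::map(tl, "descs")
  )
}

# token -> synonym map used for noisy substitution; tokens without an entry
# are dropped when selected for corruption
token_synonyms <- function() {
  c(chicken = "chook", beef = "steak", chips = "fries", fries = "chips",
    salad = "greens", fresh = "crisp", grilled = "chargrilled",
    burger = "burgr", pizza = "pizzas", drink = "bevvy", sweet = "sugary",
    large = "big", rice = "grains", soup = "broth", sauce = "dressing",
    cheese = "cheddar", milk = "dairy", juice = "nectar", meal = "combo",
    deal = "bundle", cream = "creme", hot = "warm", fried = "fryed",
    roast = "roasted", fish = "seafood", wrap = "roll", sandwich = "sammie",
    pie = "pastry", cake = "gateau", energy = "power", coffee = "espresso",
    smoothie = "blend", sushi = "maki", curry = "masala", noodle = "noodles",
    bowl = "dish", loaded = "topped", value = "budget", premium = "deluxe",
    vegetable = "veggie", vegetables = "veggies", fruit = "fruits",
    with = "and", and = "plus", golden = "crispy", classic = "original")
}

# Corrupt a token vector: each token independently selected with probability
# `rate`; selected tokens are replaced by their synonym if one exists,
# otherwise dropped. Returns the new tokens plus corruption bookkeeping.
corrupt_tokens <- function(tokens, rate, synonyms = token_synonyms()) {
  hit <- runif(length(tokens)) < rate
  out <- tokens
  has_syn <- tokens %in% names(synonyms)
  out[hit & has_syn] <- unname(synonyms[tokens[hit & has_syn]])
  keep <- !(hit & !has_syn)
  list(tokens = out[keep], n_tokens = length(tokens), n_corrupted = sum(hit))
}

#' Generate one synthetic menu-item text
#'
#' Draws a name and description template for the category and applies token
#' noise (synonym substitution where a synonym is defined, dropout
#' otherwise). With `noise_rate = 0` the text is a verbatim template. A name
#' that would be fully dropped retains its first original token so the
#' non-empty-name invariant always holds.
#'
#' @param category A category name present in `templates`.
#' @param seed Optional integer seed (deterministic text for a fixed seed);
#'   `NULL` draws from the current RNG stream.
#' @param noise_rate Per-token corruption probability in \[0, 1\].
#' @param templates Template table from [category_templates()].
#'
#' @return A one-row tibble: `name`, `description`, `truth_category`,
#'   `n_tokens`, `n_corrupted`.
#' @export
generate_item_text <- function(category, seed = NULL, noise_rate = 0,
                               templates = category_templates()) {
  gen <- function() generate_item_texts(category, noise_rate, templates)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# vectorised worker: one row per element of `categories`, drawing from the
# current RNG stream
generate_item_texts <- function(categories, noise_rate = 0,
                                templates = category_templates()) {
  assert_prob(noise_rate, "noise_rate")
  idx <- match(categories, templates$category)
  if (anyNA(idx)) {
    abort(sprintf("Unknown category '%s': no text templates defined.",
                  categories[which(is.na(idx))[1]]),
          class = "mdaudit_config_error")
  }
  syn <- token_synonyms()
  n <- length(categories)
  name <- character(n); desc <- character(n)
  n_tokens <- integer(n); n_corrupted <- integer(n)
  for (r in seq_len(n)) {
    i <- idx[r]
    nm_tokens <- strsplit(sample(templates$names[[i]], 1L), " ", fixed = TRUE)[[1]]
    ds_tokens <- strsplit(sample(templates$descs[[i]], 1L), " ", fixed = TRUE)[[1]]
    cn <- corrupt_tokens(nm_tokens, noise_rate, syn)
    cd <- corrupt_tokens(ds_tokens, noise_rate, syn)
    name[r] <- if (length(cn$tokens)) paste(cn$tokens, collapse = " ") else nm_tokens[1]
    desc[r] <- paste(cd$tokens, collapse = " ")
    n_tokens[r] <- cn$n_tokens + cd$n_tokens
    n_corrupted[r] <- cn$n_corrupted + cd$n_corrupted
  }
  tibble(name = name, description = desc, truth_category = categories,
         n_tokens = n_tokens, n_corrupted = n_corrupted)
}
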