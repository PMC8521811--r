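# Stoplight-Diet food lists per target eating behavior: green "anytime",
# yellow "sometimes", red "rarely" tiers, plus an autonomy-supportive goal
# statement. Content is editable data, seeded with generic examples.
fruit:
  goal: "You may aim for 2 or more servings of fruit each day."
  green: [apples, bananas, berries, oranges, grapes]
  yellow: [100% fruit juice (small glass), dried fruit, canned fruit in juice]
  red: [fruit snacks/gummies, canned fruit in syrup, fruit pies]
vegetable:
  goal: "You could add a vegetable to lunch and dinner to reach 2 or more a day."
  green: [carrots, broccoli, leafy salads, peppers, cucumbers]
  yellow: [vegetable soup, baked potato, corn]
  red: [french fries, fried vegetables, vegetables in cream sauce]
whole_grains:
  goal: "You may swap refined grains for whole grains at one meal a day."
  green: [whole-wheat bread, oatmeal, brown rice, whole-grain cereal]
  yellow: [white rice, flour tortillas, pretzels]
  red: [doughnuts, sweetened cereal, croissants]
ssb:
  goal: "You could replace sugary drinks with water or milk most days."
  green: [water, sparkling water, skim or 1% milk]
  yellow: [100% fruit juice (small glass), flavored milk, diet drinks]
  red: [soda, sports drinks, sweetened tea, energy drinks]
snacking:
  goal: "You may plan one healthy snack to replace a packaged snack each day."
  green: [fresh fruit, raw vegetables with hummus, plain yogurt, nuts (small handful)]
  yellow: [granola bars, crackers and cheese, popcorn (lightly salted)]
  red: [chips, candy, cookies, ice cream]
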