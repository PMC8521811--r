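# Patient-facing education blocks, keyed by topic. Blocks for flagged diet
# behaviors are attached to the prescription together with the general
# physical-activity block. Bodies are written in autonomy-supportive,
# plain language and kept short for readability.
general_pa:
  title: "Why move more?"
  body: >-
    Regular activity can improve sleep, mood and energy. You may start small
    and build up a little each week. Any activity you enjoy counts.
stoplight_overview:
  title: "Green, yellow and red foods"
  body: >-
    Green foods are great anytime. Yellow foods are fine sometimes. Red
    foods are best saved for rare treats. You could use the colors to plan
    meals and snacks.
fruit:
  title: "Enjoying more fruit"
  body: >-
    Fresh fruit makes an easy snack. You may keep washed fruit where you can
    see it, or add fruit to breakfast.
vegetable:
  title: "Adding vegetables"
  body: >-
    Vegetables can be tasty raw with a dip or roasted with a little oil. You
    could try adding one vegetable to lunch and one to dinner.
whole_grains:
  title: "Choosing whole grains"
  body: >-
    Whole grains keep you full longer. You may swap white bread for
    whole-wheat, or try oatmeal in the morning.
ssb:
  title: "Rethinking sugary drinks"
  body: >-
    Sugary drinks add up fast. Water, sparkling water or milk could take
    their place most days. A small change here can make a big difference.
snacking:
  title: "Smart snacking"
  body: >-
    Planning snacks ahead can help. You may keep fruit, vegetables or yogurt
    ready for after school instead of chips or candy.
tips_for_families:
  title: "Tips for parents and families"
  body: >-
    Change is easier together. Families may plan active time together and
    keep green foods easy to reach at home.
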