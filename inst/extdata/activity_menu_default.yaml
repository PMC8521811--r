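# Menu of youth activities the patient chooses from, with MET values in the
# style of the Compendium of Physical Activities. intensity must equal the
# MET-band classification (light < 3.0, moderate 3.0-<6.0, vigorous >= 6.0);
# this is checked at load time. Tags support region/family filtering.
- {name: "walking the dog",        met: 3.0,  intensity: moderate, tags: [family_oriented, outdoor]}
- {name: "brisk walking",          met: 3.5,  intensity: moderate, tags: [outdoor, indoor]}
- {name: "swimming (leisure)",     met: 5.5,  intensity: moderate, tags: [outdoor, seasonal]}
- {name: "swimming laps",          met: 7.0,  intensity: vigorous, tags: [seasonal]}
- {name: "playing basketball",     met: 6.5,  intensity: vigorous, tags: [team, outdoor, indoor]}
- {name: "soccer (casual)",        met: 7.0,  intensity: vigorous, tags: [team, outdoor]}
- {name: "bicycling (leisure)",    met: 4.0,  intensity: moderate, tags: [outdoor, family_oriented]}
- {name: "dancing",                met: 5.0,  intensity: moderate, tags: [indoor, family_oriented]}
- {name: "jump rope",              met: 10.0, intensity: vigorous, tags: [indoor, outdoor]}
- {name: "hiking",                 met: 5.3,  intensity: moderate, tags: [outdoor, family_oriented]}
- {name: "skateboarding",          met: 5.0,  intensity: moderate, tags: [outdoor]}
- {name: "yoga",                   met: 2.5,  intensity: light,    tags: [indoor]}
- {name: "stretching",             met: 2.3,  intensity: light,    tags: [indoor]}
- {name: "playing catch",          met: 2.5,  intensity: light,    tags: [family_oriented, outdoor]}
- {name: "active video games",     met: 3.8,  intensity: moderate, tags: [indoor]}
- {name: "surfing",                met: 3.5,  intensity: moderate, tags: [outdoor, coastal]}
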