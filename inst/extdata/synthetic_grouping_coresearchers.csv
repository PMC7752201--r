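quote,group
ID01,green
ID02,blue
ID03,pink
ID04,blue
ID05,green
ID06,blue
ID07,pink
ID08,pink
ID09,green
ID10,pink
ID11,green
ID12,blue
ID13,pink
ID14,blue
ID15,blue
ID16,pink
ID17,blue
ID18,green
ID19,blue
ID20,blue
ID21,pink
ID22,green
ID23,blue
ID24,green
ID25,green
ID26,green
ID27,pink
ID28,green
ID29,pink
ID30,pink
ID31,green
ID32,green
ID33,blue
ID34,green
ID35,pink
ID36,pink
ID37,pink
ID38,pink
ID39,green
ID40,blue
ID41,blue
ID42,green
ID43,pink
ID44,green
ID45,green
ID46,pink
ID47,blue
ID48,blue
ID49,blue
ID50,blue
ID51,pink
ID52,green
ID53,blue
ID54,green
ID55,pink
ID56,green
ID57,green
ID58,pink
ID59,pink
ID60,blue
ID61,pink
ID62,green
ID63,green
ID64,pink
ID65,pink
ID66,blue
ID67,blue
ID68,green
ID69,blue
ID70,blue
ID71,blue
ID72,pink
ID73,green
ID74,pink
ID75,blue
ID76,pink
ID77,pink
ID78,green
ID79,green
ID80,blue
ID81,pink
ID82,blue
ID83,blue
ID84,pink
ID85,pink
ID86,green
ID87,pink
ID88,pink
ID89,blue
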