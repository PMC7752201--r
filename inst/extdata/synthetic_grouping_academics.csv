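quote,group
ID01,red
ID02,pink
ID03,blue
ID04,pink
ID05,green
ID06,green
ID07,pink
ID08,blue
ID09,green
ID10,red
ID11,blue
ID12,pink
ID13,blue
ID14,pink
ID15,blue
ID16,blue
ID17,blue
ID18,blue
ID19,blue
ID20,blue
ID21,red
ID22,red
ID23,blue
ID24,green
ID25,green
ID26,green
ID27,red
ID28,green
ID29,red
ID30,red
ID31,pink
ID32,red
ID33,red
ID34,green
ID35,red
ID36,red
ID37,red
ID38,blue
ID39,red
ID40,green
ID41,green
ID42,red
ID43,pink
ID44,green
ID45,green
ID46,red
ID47,green
ID48,blue
ID49,blue
ID50,red
ID51,green
ID52,blue
ID53,green
ID54,blue
ID55,green
ID56,blue
ID57,green
ID58,red
ID59,pink
ID60,green
ID61,green
ID62,green
ID63,red
ID64,blue
ID65,red
ID66,green
ID67,red
ID68,green
ID69,blue
ID70,blue
ID71,red
ID72,red
ID73,red
ID74,red
ID75,green
ID76,green
ID77,red
ID78,green
ID79,green
ID80,pink
ID81,green
ID82,red
ID83,pink
ID84,red
ID85,red
ID86,blue
ID87,green
ID88,red
ID89,pink
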