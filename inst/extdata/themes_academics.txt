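# Themes generated by the academic analyst group (subthemes listed as separate rows)
1. A social environment: 2, 4, 12, 14, 80, 89, 10
2. Unique qualities of trainers/programme: 13, 15, 18, 20, 56, 19, 8
3. Agency: 23, 49, 54
4. Physical adjustments to programme: 3, 11, 17, 52, 69, 70
5a. Physical benefits: 61, 45, 51, 66, 79, 24, 62
5b. Physical and mental benefits: 6, 75, 78
5c. Mental benefits: 5, 9, 26, 25, 34, 41, 44, 55, 57, 47, 60, 68, 76
6a. The 'gym' environment: 46, 21, 65, 73, 84, 85
6b. Barriers more generally for participants: 36, 50, 33, 74, 37, 77, 27
6c. Practical, process-related barriers: 63, 67, 71, 72, 22, 10
7. Long-term habits: 29, 32, 35, 39
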