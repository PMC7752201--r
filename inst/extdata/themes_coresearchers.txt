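# Themes generated by the co-researcher analyst group (line format: label: quote ids)
1. Social element/group dynamic: 14, 4, 2, 40, 49, 12, 80, 89
2. Preconceptions and barriers to exercise: 10, 36, 16, 46, 37, 7, 77, 74, 43, 29, 27, 81, 88, 65, 84
3. Approach from trainers to participants: 13, 87, 7, 58
4. Practical issues: 89, 22, 11, 64, 3, 54, 42, 59, 10, 71
5. Education/knowledge and awareness: 78, 24, 28, 57, 9, 32, 5, 42, 1, 62, 44, 45, 25, 54, 34, 26, 68
6. Personal responsibility: 32, 30, 83, 47, 15, 40, 69, 41, 23, 17, 19
7. Change in behaviour and perspectives: ID17, ID66, ID70, ID48, ID32, ID35, ID23
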