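# hex dump of the archive produced from golden.fastq by this
# implementation at format version 1 (synthetic input; generated
# once and reviewed); pins the on-disk format.
4651434d4152433101000000040000001400000000000000a67b4b46ae16b10b
040000000100000001000000000000004e00000000000000cfa09d229f861c17
da8f4de029b794150200000002000000d10000007b227365715f6f7264657273
223a5b322c352c382c31315d2c227365715f616c706861223a302e303632352c
227365715f6465636179223a302e39352c227365715f686173685f6269747322
3a32342c227175616c5f707265646963746f7273223a5b747275652c74727565
2c747275652c747275652c747275652c747275655d2c227175616c5f70726564
5f7368696674223a352c227175616c5f6d69785f7368696674223a31332c2271
75616c5f6275636b657473223a382c227175616c5f706f735f6275636b657473
223a31367d11010000000000004f437225903cfd724f766f7ad863f675030000
0003000000000000000e00000000000000e52f93726382d47910f8ac78c4a099
1d0400000004000000d10000007b227365715f6f7264657273223a5b322c352c
382c31315d2c227365715f616c706861223a302e303632352c227365715f6465
636179223a302e39352c227365715f686173685f62697473223a32342c227175
616c5f707265646963746f7273223a5b747275652c747275652c747275652c74
7275652c747275652c747275655d2c227175616c5f707265645f736869667422
3a352c227175616c5f6d69785f7368696674223a31332c227175616c5f627563
6b657473223a382c227175616c5f706f735f6275636b657473223a31367d3a02
00000000000000bec538f1d11f9039c6943daacfa22ec7000000060000003800
0000020800fdf8ff00eb83356f595c44d8c625f20c6825b1d72eb5e50e32e722
20a4483d6d517c32a7dc794e080203a2ef30e88196b945cc3c28535251dacddc
d1dfd1009cbe533f975e2ba389bc451beadd6fb26744c4ac981c8db0962e791f
01dfcbf1e1f2368f09fbabfb6777fdb39a2309aec15aa5eeb031824bcce17807
94cb930b41f27881e062e80f189017503f03e15e0d433d2e068cb7e1c81867ec
957a5e3b2ea328355d718dd6e101551e94de573f7a6322013b1b9da053dfe2c1
4bf497ede81a75d730376f98dfc5004e25ee6756f40ac91862b09ca12819dba0
ec21cc856409523738f40eb2e996d0f0e792a1ddd7a6f51fa09bc554741177dd
a1c29191336e9216a4ab019f54507133c6e6bcd4d0dde2967f53072e33377609
7396e19b014a599857d08be6dde94a6075ae4c4cb818f8b268c04e488cf1b7d6
5403d43cc147930ffed1cd46aa9cc088ce41d885001400000063ffff9c000000
000000c998da53f3df4b9dce6787d939b62847f77a83a1cb603b739edc1bb971
fc1b7c580762c38702830ace81a7b60af871c9f4eddce5e32575ae96bd590ddc
fbbf7e7f604ad921cd9c8f5c877b0fe5408783be6390cc48e4cdd36c0c67f899
a74fdbcc0c829d4f7799f15072709b351be83744c5bece145b29aea048e172cd
bb6f58d3ccffc004e642d17120a9d3e9a23d50da3b5d4ea41a8a8b29a6ec0d6c
a1163a951f04062a793f09ef6c49fa9d93d28c0fff3e04857518fad1cdba72d7
303c9f0dca4bb037c5f94ccb4874fd5562412fe678d13a1b6494983b21598612
94c9575af068977256f285be598d11ac57eda1bf5673eaeab420faf3772703ad
bb526f993750465b2e3012ef65d5a274193681714086065cf62b03315fc62a0e
8799b2201404f806ebeeb5cbf0b2f6b9413f62717b59c4eb63aeb087ce257b7b
30e59bdc2aa0c78f31099813d7c8cb15c73c49db99de89eff6f7029f92216593
e964b4c55404b38125957c355dfc64ecba7eef3b25eb869d2ca45543882acdac
7d8584c186e2e39405f1f64df5d6a78e4781b363b97a870355fae6f05b2f1cae
4cd2ed447327fb6770fab6734f5c16fb6d88793334a552348602efb74c020088
c6a2037faa7e719d0f182ac582082ce9754036dc8e69baf2a78fa9b8d57cd3f5
214115f4edeca6b926cd2c60baf8a48ce985b175fff0518d6445ec41601af291
ff0d34d3eab8204b73c28f7f4b00cae5a4564ef34b30c43e4f6a0ca7eb1b93c7
ffb344faba3e3e019b0b0f6e668cb4d0ebe2f39b9e715251a0e7430000
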