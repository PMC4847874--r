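// Generated closed-form evaluation of E = int int dt ds / q(t,s)^2
// and its six partial derivatives dE/d(a,b,c,d,e,f).
// Produced by symbolic differentiation with common-subexpression
// elimination of the partial-fraction closed form; verified against
// the templated reference kernel and adaptive quadrature in tests.
#ifndef CM_EXCLVOL_GEN_H
#define CM_EXCLVOL_GEN_H
#include <cmath>
namespace cm {
inline void exclKernelGen(double a, double b, double c, double d,
                          double e, double f, double* out) {
    const double x0 = 2*d;
    const double x1 = a + f + x0;
    const double x2 = x1/f;
    const double x3 = std::log(x2);
    const double x4 = std::pow(e, 2);
    const double x5 = a*x4;
    const double x6 = std::pow(b, 2);
    const double x7 = f*x6;
    const double x8 = b*e;
    const double x9 = x0*x8;
    const double x10 = x7 - x9;
    const double x11 = x10 + x5;
    const double x12 = 1.0/x11;
    const double x13 = x12*x3;
    const double x14 = c*f;
    const double x15 = x14 - x4;
    const double x16 = 1.0/x15;
    const double x17 = a*c;
    const double x18 = -x6;
    const double x19 = x17 + x18;
    const double x20 = 2*x8;
    const double x21 = c*x0;
    const double x22 = -x20 + x21;
    const double x23 = x15 + x19 + x22;
    const double x24 = x16*x23;
    const double x25 = std::log(x24);
    const double x26 = b*x25;
    const double x27 = x12*x26;
    const double x28 = 2*e;
    const double x29 = c - x28;
    const double x30 = f + x29;
    const double x31 = 2*b;
    const double x32 = -x31;
    const double x33 = x1 + x29 + x32;
    const double x34 = x33/x30;
    const double x35 = std::log(x34);
    const double x36 = std::pow(c, 2);
    const double x37 = a*x36;
    const double x38 = c*x6;
    const double x39 = b*c;
    const double x40 = x0*x39;
    const double x41 = x37 - x38 + x40;
    const double x42 = x11 - x17*x28 + x41;
    const double x43 = 1.0/x42;
    const double x44 = x35*x43;
    const double x45 = a*f;
    const double x46 = std::pow(d, 2);
    const double x47 = x45 - x46;
    const double x48 = std::pow(x47, -1.0/2.0);
    const double x49 = a + d;
    const double x50 = std::atan(d*x48) - std::atan(x48*x49);
    const double x51 = x48*x50;
    const double x52 = 2*x51;
    const double x53 = a*e;
    const double x54 = b*d;
    const double x55 = x53 - x54;
    const double x56 = x12*x55;
    const double x57 = x26*x43;
    const double x58 = a*x30;
    const double x59 = b - d;
    const double x60 = std::pow(x59, 2);
    const double x61 = x58 - x60;
    const double x62 = std::pow(x61, -1.0/2.0);
    const double x63 = -x59;
    const double x64 = std::pow(x63, 2);
    const double x65 = x58 - x64;
    const double x66 = std::pow(x65, -1.0/2.0);
    const double x67 = -b + x49;
    const double x68 = std::atan(x63*x66) - std::atan(x66*x67);
    const double x69 = x62*x68;
    const double x70 = 2*x69;
    const double x71 = b*x59;
    const double x72 = 2*x6;
    const double x73 = b*x0;
    const double x74 = -x53;
    const double x75 = x17 + x74;
    const double x76 = -x72 + x73 + x75;
    const double x77 = x71 + x76;
    const double x78 = x43*x77;
    const double x79 = c*d;
    const double x80 = -x79;
    const double x81 = x8 + x80;
    const double x82 = std::pow(x81, 2);
    const double x83 = x15*x19;
    const double x84 = -x82 + x83;
    const double x85 = std::pow(x84, -1.0/2.0);
    const double x86 = -x81;
    const double x87 = std::pow(x86, 2);
    const double x88 = x83 - x87;
    const double x89 = std::pow(x88, -1.0/2.0);
    const double x90 = x19 + x79 - x8;
    const double x91 = std::atan(x86*x89) - std::atan(x89*x90);
    const double x92 = x85*x91;
    const double x93 = 2*x92;
    const double x94 = b*x81;
    const double x95 = e*x17;
    const double x96 = e*x6;
    const double x97 = -x40 + x95 + x96;
    const double x98 = -x94 + x97;
    const double x99 = x12*x98;
    const double x100 = x41 + x94 - x95 - x96;
    const double x101 = x43*x93;
    const double x102 = std::pow(x15, -1.0/2.0);
    const double x103 = c - e;
    const double x104 = std::atan(e*x102) + std::atan(x102*x103);
    const double x105 = x102*x104;
    const double x106 = x105*x86;
    const double x107 = std::pow(x23, -1.0/2.0);
    const double x108 = b + e;
    const double x109 = std::atan(x107*x108);
    const double x110 = -c;
    const double x111 = x108 + x110;
    const double x112 = -x111;
    const double x113 = x109 + std::atan(x107*x112);
    const double x114 = c*x46;
    const double x115 = a*x14;
    const double x116 = x114 - x115;
    const double x117 = x11 + x116;
    const double x118 = b*x117;
    const double x119 = 1.0/x19;
    const double x120 = x38*x46;
    const double x121 = std::pow(a, 2);
    const double x122 = x121*x4;
    const double x123 = c*x122;
    const double x124 = x121*x36;
    const double x125 = f*x124;
    const double x126 = x37*x46;
    const double x127 = x125 - x126;
    const double x128 = -x123 + x127;
    const double x129 = std::pow(b, 4);
    const double x130 = f*x129;
    const double x131 = x5*x6;
    const double x132 = std::pow(b, 3);
    const double x133 = e*x0*x132;
    const double x134 = 2*x17;
    const double x135 = x130 + x131 - x133 - x134*x7;
    const double x136 = x120 + x128 + x135 + x17*x9;
    const double x137 = x119*x136;
    const double x138 = x137*x26;
    const double x139 = f*x132;
    const double x140 = d*x139;
    const double x141 = std::pow(d, 3);
    const double x142 = c*x31;
    const double x143 = x141*x142;
    const double x144 = x5*x54;
    const double x145 = e*x121;
    const double x146 = x14*x145;
    const double x147 = -2*a*b*c*d*f - a*c*e*x46 - 2*e*x46*x6 + x140 + x143 + x144 + x146;
    const double x148 = b*d*x117 - x147;
    const double x149 = x137*x94;
    const double x150 = std::pow(e, 3);
    const double x151 = x150*x6;
    const double x152 = x121*x150;
    const double x153 = x0*x132;
    const double x154 = x141*x31;
    const double x155 = x132*x4;
    const double x156 = b*x5;
    const double x157 = b*f;
    const double x158 = x0*x37;
    const double x159 = 5*x120;
    const double x160 = a*x151 + c*x152 - e*x125 + e*x126 + e*x130 + e*x159 - x0*x155 - x14*x153 - x154*x36 - 4*x156*x79 + x157*x158;
    const double x161 = x149 + x160;
    const double x162 = x118*x3 + x138 + x148*x52 - 2*x161*x85*x91;
    const double x163 = -x12*x162;
    const double x164 = x117*x71;
    const double x165 = 3*x124;
    const double x166 = x46*x6;
    const double x167 = 3*x54;
    const double x168 = 3*x38;
    const double x169 = std::pow(c, 3);
    const double x170 = x121*x169;
    const double x171 = c*x129 + x170 - x37*x72;
    const double x172 = d*x8;
    const double x173 = 4*x172;
    const double x174 = x17*x173;
    const double x175 = 2*x123 - x174;
    const double x176 = -e*x165 + x115*x73 + 4*x120 + x127 - 3*x132*x79 + x135 - x140 - x143 - x144 - x146 + x166*x28 + x167*x37 + x168*x53 + x171 + x175 + x46*x95;
    const double x177 = -x164 + x176;
    const double x178 = x36*x46;
    const double x179 = 2*x37;
    const double x180 = c*e;
    const double x181 = -a*x169*x46 + f*x170 - x122*x36 + x129*x14 - x153*x180 + x178*x6 - x179*x7 + x37*x9 + x38*x5;
    const double x182 = x161 + x181;
    const double x183 = x118*x35 + x138 + x177*x70 - 2*x182*x85*x91;
    const double x184 = -x183;
    const double x185 = 1.0/x84;
    const double x186 = c*x185;
    const double x187 = 1.0/x1;
    const double x188 = std::pow(x11, -2);
    const double x189 = 1.0/x23;
    const double x190 = x189*x39;
    const double x191 = x12*x190;
    const double x192 = 1.0/x33;
    const double x193 = x192*x43;
    const double x194 = b*x193;
    const double x195 = std::pow(x47, -3.0/2.0);
    const double x196 = f*x195;
    const double x197 = -2*c*e + x36 + x4;
    const double x198 = std::pow(x42, -2);
    const double x199 = 1.0/x47;
    const double x200 = d/(x199*x46 + 1);
    const double x201 = f*x199*x200;
    const double x202 = x199*x49;
    const double x203 = f*x202 - 2;
    const double x204 = 1.0/(x199*std::pow(x49, 2) + 1);
    const double x205 = -2*b*d + x53;
    const double x206 = -x12*x205;
    const double x207 = std::pow(x61, -3.0/2.0);
    const double x208 = x207*x68;
    const double x209 = x208*x78;
    const double x210 = std::pow(x84, -3.0/2.0);
    const double x211 = x12*x4;
    const double x212 = x12*x93;
    const double x213 = 1.0/x65;
    const double x214 = -x30;
    const double x215 = 1.0/(x213*x64 + 1);
    const double x216 = x215*x63;
    const double x217 = std::pow(x67, 2);
    const double x218 = 1.0/(x213*x217 + 1);
    const double x219 = x213*x67;
    const double x220 = x213*x214*x216 - x218*(x214*x219 + 2);
    const double x221 = x197*x43;
    const double x222 = x43*x70;
    const double x223 = -x37 + x38 + x97;
    const double x224 = x85*x99;
    const double x225 = 1.0/(x185*x82 + 1);
    const double x226 = x225*x81;
    const double x227 = std::pow(x90, 2);
    const double x228 = 1.0/(x185*x227 + 1);
    const double x229 = 1.0/x88;
    const double x230 = x229*x90;
    const double x231 = x15*x230 - 2;
    const double x232 = c*(x15*x210*x226 + x228*x231*x89);
    const double x233 = x100*x43;
    const double x234 = x233*x85;
    const double x235 = x106 - x107*x113*x90;
    const double x236 = c*x229;
    const double x237 = x15*x236;
    const double x238 = x90/std::pow(x23, 3.0/2.0);
    const double x239 = x113*x238;
    const double x240 = x108/(std::pow(x108, 2)*x189 + 1);
    const double x241 = 1.0/(std::pow(x112, 2)*x189 + 1);
    const double x242 = x90*(x112*x241 + x240)/std::pow(x23, 2);
    const double x243 = -x117;
    const double x244 = b*x243;
    const double x245 = x244*x3;
    const double x246 = -x136;
    const double x247 = x119*x246;
    const double x248 = x247*x26;
    const double x249 = -x147 - x243*x54;
    const double x250 = -x50;
    const double x251 = 2*x250*x48;
    const double x252 = b*x86;
    const double x253 = x247*x252;
    const double x254 = x160 + x253;
    const double x255 = -x254;
    const double x256 = -x91;
    const double x257 = 2*x89;
    const double x258 = x256*x257;
    const double x259 = x244*x35;
    const double x260 = x244*x63;
    const double x261 = x176 - x260;
    const double x262 = -x68;
    const double x263 = 2*x66;
    const double x264 = x262*x263;
    const double x265 = -x181 - x254;
    const double x266 = x4*x54;
    const double x267 = x115*x28;
    const double x268 = 1.0/a;
    const double x269 = 2*a;
    const double x270 = -x14*x269;
    const double x271 = x268*(-x10 - x114 - x270 - 2*x5);
    const double x272 = -x147;
    const double x273 = -x160;
    const double x274 = x4*x6;
    const double x275 = -2*c*x7 + f*x179 - x178 + x274;
    const double x276 = x119*(2*a*c*x4 - x21*x8 - x275);
    const double x277 = std::pow(x19, -2);
    const double x278 = -2*a*e*f*x36 - 4*b*c*d*x4 - b*c*x246*x277*x86 + e*x178 + x0*x157*x36 + x134*x150 + x151 + x252*x276;
    const double x279 = b*x271;
    const double x280 = 1.0/(x229*x87 + 1);
    const double x281 = 1.0/(x227*x229 + 1);
    const double x282 = x236*(x15*x229*x280*x86 - x231*x281);
    const double x283 = c*x15*x256/std::pow(x88, 3.0/2.0);
    const double x284 = x25*x277;
    const double x285 = x190*x247 - x246*x284*x39 + x26*x276;
    const double x286 = -x197;
    const double x287 = x286*x43;
    const double x288 = e*x37;
    const double x289 = 4*x5;
    const double x290 = x160 + x181;
    const double x291 = -x290;
    const double x292 = std::pow(x65, -3.0/2.0);
    const double x293 = d*e;
    const double x294 = x157 - x293;
    const double x295 = x294*x31;
    const double x296 = x188*x295;
    const double x297 = x108*x189;
    const double x298 = x297*x31;
    const double x299 = x119*x25;
    const double x300 = x299*x72;
    const double x301 = 3*x6;
    const double x302 = x17 - x301;
    const double x303 = x299*x302;
    const double x304 = x198*x35;
    const double x305 = -x157 + x293 + x39 + x80;
    const double x306 = x305*x31;
    const double x307 = x198*x25;
    const double x308 = x12*x73;
    const double x309 = 2*x12;
    const double x310 = 2*x43;
    const double x311 = b*x15;
    const double x312 = e*x81 + x311;
    const double x313 = x210*x312*x91;
    const double x314 = x62*x78;
    const double x315 = x263*(x215*(x213*x59*x63 - 1) - x218*(x219*x59 - 1));
    const double x316 = x31*x59;
    const double x317 = x316*x43;
    const double x318 = x305*x310;
    const double x319 = x119*x86;
    const double x320 = -x294;
    const double x321 = x309*x320;
    const double x322 = -x19;
    const double x323 = x277*x72*x86;
    const double x324 = x31*x319;
    const double x325 = x12*x320*x324;
    const double x326 = e*x86;
    const double x327 = x311 - x326;
    const double x328 = e + x31;
    const double x329 = x280*(-e + x229*x327*x86) - x281*(x229*x327*x90 - x328);
    const double x330 = x257*x329;
    const double x331 = x306*x43;
    const double x332 = x109 - std::atan(x107*x111);
    const double x333 = x107*x332;
    const double x334 = x238*x332;
    const double x335 = x111*x189;
    const double x336 = 1.0/(std::pow(x111, 2)*x189 + 1);
    const double x337 = x189*x90;
    const double x338 = 2*x185;
    const double x339 = x312*x338;
    const double x340 = x184*x43;
    const double x341 = 3*x7;
    const double x342 = -x173 + x341 + x5;
    const double x343 = x116 + x342;
    const double x344 = x117*x31;
    const double x345 = x132*x293;
    const double x346 = x301*x5;
    const double x347 = 6*x7;
    const double x348 = 3*x120 + x128 + 5*x130 - x17*x347 + x174 - 8*x345 + x346;
    const double x349 = x299*x348;
    const double x350 = x136*x284*x72;
    const double x351 = x136*x299;
    const double x352 = x12*x351;
    const double x353 = x0*x118;
    const double x354 = x161*x210;
    const double x355 = x354*x91;
    const double x356 = x161*x85;
    const double x357 = 2*x141;
    const double x358 = 6*d;
    const double x359 = a*x150*x31 + 4*e*x139 + f*x158 + 10*x114*x8 + x246*x323 - x247*x8 - x274*x358 - x289*x79 - x319*x348 - x347*x79 - x357*x36;
    const double x360 = x305*x344;
    const double x361 = x177*x59;
    const double x362 = 4*x17;
    const double x363 = b*x37;
    const double x364 = d*x38;
    const double x365 = x43*x59;
    const double x366 = x0*x288;
    const double x367 = x132*x14;
    const double x368 = x293*x38;
    const double x369 = x246*x319;
    const double x370 = 1 - x34;
    const double x371 = x194*x370;
    const double x372 = b*x35;
    const double x373 = a*x28;
    const double x374 = x134 + x18;
    const double x375 = -x373 + x374 + x73;
    const double x376 = x198*x375;
    const double x377 = b*x12;
    const double x378 = x189*(f*x16*x23 - x1);
    const double x379 = b*x43;
    const double x380 = std::atan(x59*x62) + std::atan(x62*x67);
    const double x381 = x207*x380;
    const double x382 = a*x78;
    const double x383 = std::atan(x81*x85) + std::atan(x85*x90);
    const double x384 = x383*x85;
    const double x385 = 2*x384;
    const double x386 = std::pow(x61, -2);
    const double x387 = 1.0/x61;
    const double x388 = 1.0/(x217*x387 + 1);
    const double x389 = x388*x67 + x59/(x387*x60 + 1);
    const double x390 = x386*x389;
    const double x391 = x105*x81 + x333*x90;
    const double x392 = x338*x391;
    const double x393 = a*x15 + f*x19;
    const double x394 = x0*x81 + x393;
    const double x395 = x383*x394;
    const double x396 = x210*x395;
    const double x397 = -x100;
    const double x398 = x397*x43;
    const double x399 = -a;
    const double x400 = x375*x43;
    const double x401 = x380*x62;
    const double x402 = x185*(-x0*x86 + x393);
    const double x403 = x185*(x225*(x0 + x402*x81) - x228*(x0 + x269 - x402*x90));
    const double x404 = x12*x162;
    const double x405 = x185*x404;
    const double x406 = x104/std::pow(x15, 3.0/2.0);
    const double x407 = x406*x81;
    const double x408 = e/(x16*x4 + 1);
    const double x409 = x103*x16;
    const double x410 = 1.0/(std::pow(x103, 2)*x16 + 1);
    const double x411 = b*x47;
    const double x412 = f*x145;
    const double x413 = x45*x73;
    const double x414 = x46*x53;
    const double x415 = x17*x46;
    const double x416 = x121*x14;
    const double x417 = a*x9;
    const double x418 = -x134*x46 - x269*x7 + 2*x416;
    const double x419 = x119*(-x122 + x166 + x417 + x418);
    const double x420 = a*x136*x277;
    const double x421 = x0*x139 - 4*x115*x54 + x137*x54 + 4*x141*x39 + 4*x144 - x152 - x28*x415 + x28*x416 - x419*x94 + x420*x94 - 5*x46*x96;
    const double x422 = b*x137;
    const double x423 = -x26*x419 + x26*x420 + x378*x422;
    const double x424 = x118*x192;
    const double x425 = -x370*x424;
    const double x426 = a*x177;
    const double x427 = -x390*x426;
    const double x428 = d*x132;
    const double x429 = x121*x180;
    const double x430 = a*x96;
    const double x431 = x17*x54;
    const double x432 = -x130;
    const double x433 = x182*x210;
    const double x434 = x118*x44;
    const double x435 = x137*x57;
    const double x436 = x188*x96;
    const double x437 = x103*x6;
    const double x438 = x195*x50;
    const double x439 = x438*x56;
    const double x440 = x199*(-x204*(d*x202 + 1) + 1);
    const double x441 = x12*x28;
    const double x442 = x387*(-x388*(-x387*x59*x67 + 1) + 1);
    const double x443 = c*x81;
    const double x444 = x210*x383*x443;
    const double x445 = -x228*(-x185*x81*x90 + 1) + 1;
    const double x446 = x186*x445;
    const double x447 = x12*x20;
    const double x448 = x103*x310;
    const double x449 = x31*x43;
    const double x450 = x103*x449;
    const double x451 = x186*x81;
    const double x452 = x242 + x334;
    const double x453 = x118*x187;
    const double x454 = x115*x31;
    const double x455 = x0*x95;
    const double x456 = 4*d*x96;
    const double x457 = x12*x243;
    const double x458 = 2*x367;
    const double x459 = 2*x155;
    const double x460 = x289*x39;
    const double x461 = 6*b*x178;
    const double x462 = -a*d*x36 - e*x132 + x17*x8 + x364;
    const double x463 = x12*x6;
    const double x464 = x148*x438;
    const double x465 = x119*x26;
    const double x466 = x137*x190;
    const double x467 = x462*x465 + x466;
    const double x468 = x103*x72;
    const double x469 = b*x55;
    const double x470 = x3*x469;
    const double x471 = x188*x55;
    const double x472 = x54 + x75;
    const double x473 = x198*x472;
    const double x474 = x189*(e*x16*x23 - x108);
    const double x475 = -x55;
    const double x476 = x292*(x216 - x218*x67);
    const double x477 = -e*x19 + x252;
    const double x478 = x477*x91;
    const double x479 = x210*x478;
    const double x480 = x31*x81;
    const double x481 = x480*x56;
    const double x482 = 2*x56;
    const double x483 = x310*x472;
    const double x484 = -x477;
    const double x485 = x280*(-b + x229*x484*x86) - x281*(-b + x229*x484*x90);
    const double x486 = x485*x89;
    const double x487 = x185*x477;
    const double x488 = x137*x6;
    const double x489 = 3*x123;
    const double x490 = x428 + x429;
    const double x491 = -x430 - x431 + x490;
    const double x492 = -b*x119*x25*x491 + x422*x474;
    const double x493 = -x132*x21 + x37*x73;
    const double x494 = x208*x426 + x425;
    const double x495 = 1 - x2;
    const double x496 = a*(x200 - x204*x49)/std::pow(x47, 2);
    const double x497 = 1 - x24;
    const double x498 = x384*x72;
    const double x499 = c*x19;
    const double x500 = std::pow(x84, -2);
    const double x501 = x226 + x228*x90;
    const double x502 = x499*x500*x501;
    const double x503 = x186*x19;
    const double x504 = b*x19;
    const double x505 = -x17*x73 + x490;
    const double x506 = x12*x132;
    const double x507 = -2*a*c*x6 + x124 + x129;
    const double x508 = -e*x124 + e*x129 - x119*x252*x507 + x493;
    const double x509 = x117*x132;
    const double x510 = -x465*x507 - x466*x497;
    const double x511 = x43*x6;
    const double x512 = x132*x43;
    out[0] = (1.0/4.0)*b*x13 - 1.0/4.0*b*x44 - 1.0/4.0*x100*x101 + (1.0/4.0)*x186*(-2*x106 + 2*x107*x113*x90 - x163 + x184*x43) - 1.0/4.0*x27 + (1.0/4.0)*x52*x56 + (1.0/4.0)*x57 + (1.0/4.0)*x70*x78 - 1.0/4.0*x93*x99;
    out[1] = (1.0/4.0)*b*c*x189*x43 + (1.0/4.0)*b*x12*x187 + (1.0/4.0)*b*x188*x25*x4 - 1.0/4.0*b*x188*x3*x4 + (1.0/4.0)*b*x197*x198*x35 + (1.0/4.0)*c*x100*x15*x210*x43*x91 + (1.0/4.0)*c*x12*x15*x210*x91*x98 + (1.0/2.0)*e*x12*x48*x50*(e*x206 - x12*x172 + 1) - 1.0/4.0*x101*(c*x103 + x221*x223 - x221*x94) - 1.0/4.0*x191 - 1.0/4.0*x194 - 1.0/4.0*x196*x50*x56 - 1.0/4.0*x197*x198*x26 - 1.0/4.0*x199*x56*(x201 - x203*x204) - 1.0/4.0*x209*x30 - 1.0/4.0*x212*(x180 + x211*x94 - x211*x97) + (1.0/4.0)*x220*x43*x62*x66*x77 - 1.0/4.0*x222*(e + x110 + x221*x71 + x221*x76) - 1.0/4.0*x224*x232 - 1.0/4.0*x232*x234 - 1.0/4.0*x236*(-c*(2*x107*x113 - x239 - x242) - x12*x237*(x245 + x248 + x249*x251 + x255*x258) + x12*(-x13*x244*x4 + x187*x244 - x196*x249*x250 + x199*x249*(x201 - x203*x204) - x245*x268 - x247*x27*x4 + x251*(2*b*c*d*f + b*d*x12*x243*x4 + b*d*x243*x268 + c*e*x46 - x211*x272 - x266 - x267 - x271*x54) + x255*x282 - x255*x283 + x258*(b*x119*x12*x246*x4*x86 - x211*x273 - x278) + x279*x3 + x285) - 2*x235*x237 + x237*x43*(x248 + x258*x265 + x259 + x261*x264) - x43*(x192*x244 - x213*x220*x261 + x214*x261*x262*x292 + x244*x286*x44 + x247*x286*x57 + x258*(2*a*x36*x4 + 2*f*x36*x6 - 2*x169*x45 + x169*x46 - x253*x287 - x278 + x286*x291*x43 - x36*x9 - x38*x4) - x259*x268 + x264*(c*x289 + e*x114 + e*x168 + x14*x73 + x167*x36 + x169*x269 + x176*x287 + x260*x268 - x260*x287 - x266 - x267 + x275 - x279*x63 - 6*x288 - x36*x72 - 4*x79*x8) + x265*x282 - x265*x283 + x279*x35 + x285));
    out[2] = -1.0/4.0*x100*x310*x313 + (1.0/4.0)*x101*(x142 - x21 + x223*x318 + x302*x319 + x319*x72 + x331*x86 + x8) + (1.0/4.0)*x12*x298 - 1.0/4.0*x12*x300 - 1.0/4.0*x12*x303 - 1.0/4.0*x12*x52*(d + x205*x294*x309 + x294*x308) + (1.0/4.0)*x13 + (1.0/4.0)*x186*(x105*x28 + 2*x108*x334 - x12*(x13*x294*x344 + x137*x298 + x295*x352 - x3*x343 + 2*x312*x355 + x330*x356 - x349 - x350 - x52*(d*x343 - d*(2*x114 + x270 + x342) + 2*x12*x147*x294 - x12*x294*x353) + x93*(x246*x325 - x273*x321 + x359)) - x163*x339 - 4*x185*x235*x312 - 2*x328*x333 + 2*x337*(-x336*(x108*x335 + 1) + 1) + x339*x340 + x43*(2*b*x108*x119*x136*x189 + 2*b*x117*x192 - x177*x315*x62 + 2*x182*x210*x312*x91 + 2*x182*x329*x85*x89 - 2*x208*x361 - x331*x351 - x343*x35 - x349 - x350 - x360*x44 - x70*(6*a*b*c*e + 2*a*b*x4 + 2*a*c*d*f + 3*a*d*x36 + 8*b*c*x46 + 4*b*e*x46 - 4*b*x115 + 4*c*x132 - c*x357 - d*x341 - d*x5 + 4*f*x132 - x118 + 2*x176*x305*x43 - x293*x362 - x343*x59 - x358*x96 - x360*x365 - 4*x363 - 9*x364) + 2*x85*x91*(x142*x5 - 4*x157*x37 + x178*x31 - x291*x318 + x331*x369 + x359 + x366 + 4*x367 - 6*x368))) + (1.0/4.0)*x193*x31 + (1.0/4.0)*x208*x310*x59*x77 + (1.0/4.0)*x212*(-x119*x322*x8 + x22 - x302*x319 - x321*x97 + x322*x323 + x322*x325) - 1.0/4.0*x222*(-d - x305*x317 - x318*x76 - x32) - 1.0/4.0*x224*x330 - 1.0/4.0*x234*x330 + (1.0/4.0)*x25*x296 - 1.0/4.0*x296*x3 - 1.0/4.0*x298*x43 + (1.0/4.0)*x300*x43 + (1.0/4.0)*x303*x43 - 1.0/4.0*x304*x306 + (1.0/4.0)*x306*x307 - 1.0/4.0*x309*x313*x98 + (1.0/4.0)*x314*x315 - 1.0/4.0*x44;
    out[3] = -1.0/4.0*x183*x185*x43 + (1.0/4.0)*x186*(-f*x407 - x0*x105 - x1*x334 + 2*x107*x332*x49 - x12*(x161*x403 + x3*x411 + x354*x395 + x385*x421 + x423 + x52*(x154 + x412 - x413 - x414 + x47*x54)) - x16*x81*(f*x16*x408 - x410*(-f*x409 + 2)) + x183*x185*x394*x43 + x189*x90*(-x1*x189*x240 + x336*(x1*x335 + 2)) - x392*x394 - x394*x405 + x43*(x182*x403 + x35*x411 + x375*x434 + x375*x435 - x381*x426 + x385*(-2*x120 - 3*x125 + 3*x126 - x131 + x133 + x149*x400 + x175 + x290*x400 + x362*x7 + x421 + x432) + x395*x433 + 2*x401*(-a*x173 - 4*a*x38 + 2*x122 + x129 - x154 + x164*x400 + x165 + 4*x166 - x176*x400 - x412 + x413 + x414 + x418 - 3*x428 - 6*x429 + 3*x430 + 6*x431 + x47*x71) + x423 + x425 + x427)) - 1.0/4.0*x26*x376 - 1.0/4.0*x310*x384*(b*x375*x43*x81 - x223*x400 - x374 - x54 - x74) + (1.0/4.0)*x310*x401*(x399 + x400*x71 + x400*x76) - 1.0/4.0*x371 + (1.0/4.0)*x372*x376 + (1.0/4.0)*x377*x378 - 1.0/4.0*x378*x379 + (1.0/4.0)*x381*x382 + (1.0/4.0)*x382*x390 + (1.0/4.0)*x385*x56 + (1.0/4.0)*x392 + (1.0/4.0)*x396*x398 - 1.0/4.0*x396*x99 + (1.0/4.0)*x398*x403 - 1.0/4.0*x403*x99 + (1.0/4.0)*x405;
    out[4] = (1.0/2.0)*d*x439 + (1.0/2.0)*x186*(c*x183*x185*x43*x81 - c*(x105 - x333 + x452) + x12*(-c*x356*x89*(-x281*(x230*x86 + 1) + 1) + d*x464 + x117*x13*x96 + x148*x440 - x3*x94 + x352*x96 + x355*x443 + x453 + x467 - x51*(6*b*x114 + x0*x457*x96 + x0*x94 + x139 + x156 + x244 - x272*x447 - x454 - x455 - x456) - x92*(f*x31*x37 + x247*x39 - x273*x447 + x28*x369*x463 - x324*x462 + x366 + 10*x368 - x458 - x459 - x460 - x461)) - 2*x391*x451 - x404*x451 + x43*(b*x35*x81 + c*x182*x185*x445 + c*x182*x210*x383*x81 + x103*x117*x35*x43*x6 + x103*x119*x136*x25*x43*x6 - x177*x442 - x361*x381 - x384*(2*a*b*e*x36 + 2*a*b*f*x36 + 2*a*d*e*x36 - a*x0*x169 + 2*b*x119*x462*x81 + 10*c*d*e*x6 - c*x132*x28 + 2*d*x36*x6 - x137*x39 - x137*x43*x468*x81 - x290*x450 - x458 - x459 - x460 - x461) - x401*(4*a*b*c*e + a*b*x4 + 2*a*d*x36 + 6*b*c*x46 + 2*b*x103*x176*x43 + 3*c*x132 + 2*e*x132 + f*x132 - x117*x365*x468 - x118 - x316*x81 - 3*x363 - 8*x364 - x454 - x455 - x456) - x424 - x467)) + (1.0/2.0)*x187*x377 + (1.0/2.0)*x190*x43 - 1.0/2.0*x191 - 1.0/2.0*x194 - 1.0/2.0*x25*x436 + (1.0/2.0)*x3*x436 + (1.0/2.0)*x304*x437 - 1.0/2.0*x307*x437 - 1.0/2.0*x377*x384*(c - x441*x97 + x447*x81) + (1.0/2.0)*x377*x51*(x12*x9 + x205*x441 - 1) + (1.0/2.0)*x379*x384*(c + x223*x448 - x450*x81) + (1.0/2.0)*x379*x401*(x103*x317 + x448*x76 - 1) + (1.0/2.0)*x381*x59*x78 + (1.0/2.0)*x398*x444 + (1.0/2.0)*x398*x446 + (1.0/2.0)*x440*x56 + (1.0/2.0)*x442*x78 - 1.0/2.0*x444*x99 - 1.0/2.0*x446*x99;
    out[5] = (1.0/2.0)*a*x209 + (1.0/2.0)*a*x314*x476 + (1.0/2.0)*x12*x51*(a - 2*x206*x475 + x308*x475) - 1.0/2.0*x12*x92*(x17 + x481 - x482*x97) + (1.0/2.0)*x186*(b*x105 - b*x107*x113 + x108*x239 - x12*(b*x117*x12*x3*x55 + b*x119*x12*x136*x25*x55 + x161*x485*x85*x89 - x354*x478 - x470 - x492 - x51*(x147*x482 - x353*x56 + x415 - x416 - x417 + x46*x72 + x55*x73) - x92*(x119*x480*x491 + x127 + x137*x481 - x159 + x160*x482 + 8*x17*x172 + 4*x345 - x346 + x432 - x488 - x489)) - x16*x86*(x410*(e*x409 - 1) + 1) + x163*x487 + x235*x338*x477 - x326*x406 + x337*(x241*(x112*x297 - 1) + 1) - x340*x487 + x43*(x182*x485*x85*x89 - x35*x469 - x426*x476*x62 - x433*x478 - x434*x472 - x435*x472 - x492 - x494 - x69*(a*c*x46 + 3*a*c*x6 + 2*a*e*x6 + 4*c*e*x121 - x153 - x165 + 2*x176*x43*x472 - x316*x55 - x344*x365*x472 - x416 - x417 - 4*x431 + 2*x46*x6) - x92*(8*a*b*c*d*e + 2*b*x119*x491*x81 + 4*d*e*x132 + 2*e*x121*x36 + x125 - x126 - x130 - x137*x449*x472*x81 - x159 - x290*x483 - x346 - x373*x38 - x488 - x489 - x493))) - 1.0/2.0*x188*x470 - 1.0/2.0*x224*x486 + (1.0/2.0)*x233*x479 - 1.0/2.0*x234*x486 + (1.0/2.0)*x26*x471 + (1.0/2.0)*x26*x473 + (1.0/2.0)*x371 - 1.0/2.0*x372*x473 - 1.0/2.0*x377*x474 + (1.0/2.0)*x379*x474 - 1.0/2.0*x43*x69*(-x317*x472 - x399 - x483*x76) - 1.0/2.0*x43*x92*(2*b*x43*x472*x81 - x17 - x223*x483) + (1.0/2.0)*x479*x99;
    out[6] = (1.0/4.0)*a*x207*x380*x43*x77 + (1.0/4.0)*a*x386*x389*x43*x77 - 1.0/4.0*a*x439 + (1.0/4.0)*b*c*x189*x43*x497 + (1.0/4.0)*b*x12*x187*x495 + (1.0/4.0)*c*x19*x210*x383*x397*x43 + (1.0/4.0)*c*x19*x397*x43*x500*x501 - 1.0/4.0*x100*x198*x498 + (1.0/4.0)*x132*x188*x25 - 1.0/4.0*x132*x188*x3 - 1.0/4.0*x132*x198*x25 + (1.0/4.0)*x132*x198*x35 - 1.0/4.0*x186*(c*x184*x185*x19*x43 + c*(x407 + x452 + x81*(x103*x410 + x408)/std::pow(x15, 2)) + x12*(a*x464 + x13*x509 + x148*x496 + x161*x502 + x3*x504 + x351*x506 - x355*x499 - x453*x495 + x510 + x52*(x19*x54 + x272*x463 - x428*x457 + x505) + x93*(x273*x463 - x369*x506 + x508)) - x163*x503 - 2*x235*x503 - x43*(x182*x502 + x35*x504 + x351*x512 + x427 - x433*x499*x91 + x44*x509 + x494 + x510 + x70*(-x124 - x129 + x176*x511 - x243*x512*x63 + x269*x38 + x504*x63 + x505) + x93*(x171 + x291*x511 - x369*x512 + x508))) - 1.0/4.0*x188*x498*x98 - 1.0/4.0*x191*x497 + (1.0/2.0)*x198*x380*x6*x62*x77 - 1.0/4.0*x210*x383*x499*x99 - 1.0/4.0*x371 - 1.0/4.0*x471*x51*x72 - 1.0/4.0*x496*x56 - 1.0/4.0*x502*x99;
}
} // namespace cm
#endif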