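ncols 27
nrows 27
xllcorner 0
yllcorner 0
cellsize 90
NODATA_value -9999
304.3 302.7 303.8 303.7 306.1 304.9 307.4 308 310.6 315.1 316.1 315.8 320.6 321.6 325.2 326.8 327 327.7 330.9 329.7 328 326.8 327 327.5 323.7 323 326.6
299.1 300.4 303.5 303.9 305.2 307.1 309.1 306.8 311.9 313.5 317.1 316 321.1 322.7 324.6 330.2 331.5 332 330.2 330.9 331.1 330.2 330.4 329.9 326 325.5 327.6
299.9 301.5 300.6 303.4 304.7 308.2 310.1 312.4 311.3 318.5 318.2 320.7 325.1 329.2 328.7 335.7 336.4 336.2 337 335.1 338.1 334.1 336 331.2 330.9 327.2 327.2
300.4 300.7 303.5 303 306.3 307.6 308.6 311 313.4 316.2 318.8 324.9 326.9 330.9 338 337.3 337 341.2 338.9 340.3 341.8 340 336.8 331.6 334.5 329.7 326.3
299.6 303.1 303.4 303.9 306.8 309.1 310.2 310.5 314.8 318.4 322.6 326 329.2 334.1 338.9 339.3 344.7 346.2 346.8 346.3 344.2 341.8 338.5 336.9 332.9 330.6 331.1
299.7 302.2 301.9 304 307 305.7 311.2 312.7 314.2 317.1 327.7 328.6 332.2 336.8 342.6 344.6 346.3 348.8 350.9 349 346.3 346.7 340 335.1 336.2 331.3 333.9
302.2 302 303.4 304.2 304.9 306.9 311.1 314 318.3 322.1 326.7 329.6 336.1 337 343.8 344.8 352.7 349.6 351.9 347.7 347.9 349.1 341.2 341.1 335.3 331.3 332.4
300.9 301.5 303.6 302 308.7 308.6 308 312.5 318.1 319.3 327.3 330.6 335.9 339.9 346.3 350.5 350.1 352.8 353.3 354.1 349.1 346.9 344.5 339.7 337.2 335.1 330
301.4 301.3 304.2 305.6 304.5 308.7 307.4 313.9 316.7 317.3 328.6 329.8 338.1 345.2 343 350.5 351.9 354.1 356.5 354.7 350.8 347.7 344.2 340.8 336.6 334 331.2
304.4 303.6 304.4 307.2 308 309.1 311.6 313 319.3 319.5 328.1 333.8 336.6 341.6 347.2 349.8 354.8 355.7 352.2 352.7 348.5 346.4 344.4 341.2 336.7 332.2 332.2
301.6 300.5 303.8 303.7 307.7 308.1 312.3 314.4 316.9 320.5 328.5 329.8 335 336.4 342.6 348.7 351.3 351.4 350.7 350 349 345.7 343.3 341.2 336.5 335.3 332.4
305.2 301.9 304.9 305.4 306.5 306.6 308.2 315.9 314.9 319.3 325.1 327 331.7 337.5 341.3 343.6 347.1 348.6 351.3 345.4 348.8 344.9 341.3 338 338 333.2 327.3
304.5 302.5 304.3 304.7 303.5 308.3 310.6 313.5 314.5 317.6 320.1 328.1 328.9 334.8 337.3 341.9 344.6 344.4 346.7 345.1 341.7 341.2 339.5 336 334.4 329.9 328.9
301.5 303.8 304.8 305.5 307.9 307.7 309.5 311.3 311.2 316.1 319.6 325.5 329.3 332.5 335 337.2 337.8 340.7 340.4 337.3 339.5 338.3 335.6 335.2 331.8 331.5 327
303.8 300.9 304.8 303.2 306.3 305.1 309.6 311.4 314.3 318.2 318.7 323.5 325 327.1 329.5 332 333.4 334.2 336.5 337.6 335.6 333.7 333.7 331.6 331.2 327.4 326.5
301.6 301.4 303.9 305.6 304.8 305.9 309.9 311.6 311 314.1 315.8 322 323.8 325.2 326.3 326.6 329.7 334.9 331.7 332.8 331 331.7 330.1 327.4 329.4 326.9 326.6
299.6 299.8 303.4 301.4 305.9 307.7 307.7 307.2 310.8 313 315.1 313.1 318.1 322.7 324.2 326.7 326.7 328.3 327.7 327.9 328.5 327.4 327.6 325.6 325.1 325.3 325.8
300.4 301.2 301.3 302.9 306.9 304.4 306.1 307.4 309.5 310.4 314 316.3 315.6 322.3 321.5 322.3 323.1 325.4 326.9 324.9 326 326.4 327.4 326.7 324.5 326.3 324.9
300.9 301.1 301.7 303.3 305.2 305.2 309.9 308.4 311.4 308.3 311.9 315.5 312.9 318.4 319.4 322.2 319.1 324.3 321.5 323.6 325.2 325.8 322.7 324.6 322.1 320.5 322.1
302.3 303.7 301.2 304.2 304.4 306.3 309.8 305.3 306.4 314 312.6 313.1 311.5 312.9 315 316.5 321.9 319.3 317.4 321 323 322.3 322.2 323.5 322.6 324.5 322
302.1 302.5 300 304.2 302 303.9 307.8 308.9 308.1 310.8 309.4 309.8 311.5 315.5 314.1 317.8 316 317.9 317.4 321.3 319.4 322.3 321.3 319.3 321 321.2 322.9
301.9 301.8 300.5 303.2 305.7 302.6 305.6 306.9 307.9 310.2 312.3 310.4 313.6 313.8 315.4 315.5 315.6 316.8 316.7 318.3 318.7 318.6 321.2 318.1 318.3 322.1 321
302.8 303 301.1 301.5 303.2 306.7 306.5 304.3 307.6 309.2 307.9 308.2 313.3 311.9 312.8 313.1 316.7 319.4 314.9 317.2 321.9 319.2 318 320 320.4 323.5 322.5
298.7 301.2 301.6 303.7 305.3 306.7 304.9 305.6 306.8 307.4 309.2 308.5 311.3 313.1 314.6 313.6 313.1 315.2 313.4 316 316.4 315 320.4 318 319.3 321.7 323
302.7 301.6 302.3 300.8 305.3 304.8 307.3 305.6 306.7 308.3 306.3 308.9 311 310.1 311.6 315 312.5 315.2 315.2 314.6 318.4 321.6 318.3 318.7 320.2 319.9 320.3
301.1 302.2 306 304.7 304.6 305.3 306.3 305.1 307.5 306.8 309 313.2 311.4 312.3 314.2 313.9 312.6 314.3 318.7 315.3 317.1 319.3 320.9 317.8 320 322.9 321.2
301.9 304.2 302.9 304.7 305.7 305 302.9 308.7 305.8 310.1 308.5 309.8 311.3 311.8 314.3 312.4 314.6 315.8 317.5 315.9 314.5 318.7 319.1 319.3 319.8 320.6 321.5
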